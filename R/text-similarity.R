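#' Fuzzy string similarity: partial token sort ratio
#'
#' Product names in marketing databases ("Children's Breakfast Cereals,
#' President's Choice") and reference food descriptions ("Cereal, ready to
#' eat, ...") rarely agree verbatim, but they often share tokens in a
#' different order, embedded in longer strings.  The partial token sort
#' ratio handles both nuisances at once: both strings are normalized and
#' their tokens sorted, and the shorter string is then compared against
#' every same-length window of the longer one, keeping the best
#' Ratcliff/Obershelp similarity.  Scores live on an integer 0-100 scale:
#' 0 means no similarity, 100 near-exact similarity.
#'
#' `partial_token_sort_ratio()` is the user-facing entry point and accepts
#' raw strings; the component operations (`normalize_text()`,
#' `token_sort()`, `similarity_ratio()`, `partial_ratio()`) are exported
#' so each stage can be inspected and tested on its own.
#'
#' @param a,b Character strings to compare. `partial_token_sort_ratio()`
#'   is vectorized over pairs and recycles length-1 arguments.
#' @return An integer score in `[0, 100]`.
#' @examples
#' partial_token_sort_ratio("milk chocolate", "chocolate milk!") # 100
#' partial_token_sort_ratio("abcd", "wxyz")                      # 0
#' @name text_similarity
NULL

#' Normalize a string for fuzzy comparison
#'
#' Lowercases, replaces every non-alphanumeric character with a space,
#' collapses runs of whitespace, and trims. All comparisons in the fuzzy
#' scoring pipeline operate on normalized text.
#'
#' @param s Character vector.
#' @return Character vector of normalized strings.
#' @examples
#' normalize_text("  Cheese,   blue ") # "cheese blue"
#' @export
normalize_text <- function(s) {
  s <- tolower(as.character(s))
  s <- gsub("[^a-z0-9]+", " ", s)
  s <- gsub("^ +| +$", "", s)
  s
}

#' Sort the tokens of a normalized string
#'
#' Splits on spaces, sorts tokens in plain byte order (no locale
#' collation), and rejoins with single spaces. Duplicate tokens are kept.
#'
#' @param s Character vector of already-normalized strings.
#' @return Character vector with tokens sorted.
#' @export
token_sort <- function(s) {
  vapply(strsplit(as.character(s), " ", fixed = TRUE), function(tok) {
    tok <- tok[nzchar(tok)]
    paste(sort(tok, method = "radix"), collapse = " ")
  }, character(1))
}

# Longest matching block between a[alo:ahi] and b[blo:bhi] (character
# vectors), ties broken by smallest start in a, then smallest start in b.
# Returns c(i, j, size) or size 0.
longest_match <- function(a, b, alo, ahi, blo, bhi) {
  besti <- alo; bestj <- blo; bestsize <- 0L
  if (ahi < alo || bhi < blo) return(c(besti, bestj, bestsize))
  # j2len[j] = length of longest match ending at a[i], b[j]
  j2len <- integer(bhi)
  for (i in alo:ahi) {
    newj2len <- integer(bhi)
    js <- which(b[blo:bhi] == a[i]) + blo - 1L
    for (j in js) {
      k <- if (j > blo) j2len[j - 1L] + 1L else 1L
      newj2len[j] <- k
      if (k > bestsize) {
        besti <- i - k + 1L
        bestj <- j - k + 1L
        bestsize <- k
      }
    }
    j2len <- newj2len
  }
  c(besti, bestj, bestsize)
}

# Total length M of matching blocks under the recursive longest-block
# decomposition (leftmost-longest tie rule).
matching_total <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) return(0L)
  total <- 0L
  # Explicit stack of (alo, ahi, blo, bhi) regions.
  stack <- list(c(1L, length(a), 1L, length(b)))
  while (length(stack)) {
    reg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    m <- longest_match(a, b, reg[1], reg[2], reg[3], reg[4])
    if (m[3] > 0L) {
      total <- total + m[3]
      if (m[1] > reg[1] && m[2] > reg[3]) {
        stack[[length(stack) + 1L]] <- c(reg[1], m[1] - 1L, reg[3], m[2] - 1L)
      }
      if (m[1] + m[3] <= reg[2] && m[2] + m[3] <= reg[4]) {
        stack[[length(stack) + 1L]] <- c(m[1] + m[3], reg[2], m[2] + m[3], reg[4])
      }
    }
  }
  total
}

ratio_raw <- function(a_chars, b_chars) {
  na <- length(a_chars); nb <- length(b_chars)
  if (na + nb == 0L) return(100)
  200 * matching_total(a_chars, b_chars) / (na + nb)
}

#' Ratcliff/Obershelp similarity ratio of two normalized strings
#'
#' `100 * 2M / (|a| + |b|)`, rounded half-up to an integer, where `M` is
#' the total length of matching blocks under the recursive
#' longest-common-block decomposition. Two empty strings score 100; one
#' empty string scores 0.
#'
#' @inheritParams text_similarity
#' @return Integer score in `[0, 100]`.
#' @export
similarity_ratio <- function(a, b) {
  as.integer(round_half_up(ratio_raw(str_chars(a), str_chars(b))))
}

str_chars <- function(s) {
  if (is.na(s) || !nzchar(s)) character(0) else strsplit(s, "", fixed = TRUE)[[1]]
}

#' Partial ratio: best window similarity
#'
#' The shorter string is slid across the longer one; every contiguous
#' window of the longer string with the shorter string's length (plus the
#' full longer string itself) is scored with [similarity_ratio()] and the
#' maximum is returned. Windows are enumerated exhaustively, which makes
#' the score an exact maximum rather than a heuristic. Symmetric in its
#' arguments.
#'
#' @inheritParams text_similarity
#' @return Integer score in `[0, 100]`.
#' @export
partial_ratio <- function(a, b) {
  ca <- str_chars(a); cb <- str_chars(b)
  # canonical argument order (length, then byte order): the greedy
  # matching-block decomposition is directional, so equal-length pairs
  # must be scored in a fixed order for the score to be symmetric
  if (length(ca) > length(cb) ||
      (length(ca) == length(cb) &&
       paste(ca, collapse = "") > paste(cb, collapse = ""))) {
    tmp <- ca; ca <- cb; cb <- tmp
  }
  ns <- length(ca); nl <- length(cb)
  if (ns == 0L) return(if (nl == 0L) 100L else 0L)
  best <- ratio_raw(ca, cb)  # the full longer string
  if (best < 100) {
    for (start in seq_len(nl - ns + 1L)) {
      r <- ratio_raw(ca, cb[start:(start + ns - 1L)])
      if (r > best) best <- r
      if (best >= 100) break
    }
  }
  as.integer(round_half_up(best))
}

#' @rdname text_similarity
#' @export
partial_token_sort_ratio <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  ta <- token_sort(normalize_text(a))
  tb <- token_sort(normalize_text(b))
  vapply(seq_len(n), function(i) partial_ratio(ta[i], tb[i]), integer(1))
}
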