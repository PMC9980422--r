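# Independently coded brute-force oracles. These deliberately avoid the
# package's implementation route: the string oracle finds longest common
# substrings by exhaustive substring scanning (not dynamic programming),
# and the sift oracle evaluates each filter definition literally with
# plain loops.

# Longest common substring of a and b; ties resolved to the smallest
# start in a, then the smallest start in b. Returns c(i, j, size).
oracle_lcs <- function(a, b) {
  na <- nchar(a); nb <- nchar(b)
  for (size in rev(seq_len(min(na, nb)))) {
    for (i in seq_len(na - size + 1L)) {
      j <- regexpr(substr(a, i, i + size - 1L), b, fixed = TRUE)[1]
      if (j > 0L) return(c(i, j, size))
    }
  }
  c(0L, 0L, 0L)
}

# Total matched length under the recursive longest-block decomposition.
oracle_match_total <- function(a, b) {
  if (nchar(a) == 0L || nchar(b) == 0L) return(0L)
  m <- oracle_lcs(a, b)
  if (m[3] == 0L) return(0L)
  m[3] +
    oracle_match_total(substr(a, 1L, m[1] - 1L), substr(b, 1L, m[2] - 1L)) +
    oracle_match_total(substr(a, m[1] + m[3], nchar(a)),
                       substr(b, m[2] + m[3], nchar(b)))
}

oracle_round <- function(x) as.integer(floor(x + 0.5))

oracle_ratio <- function(a, b) {
  n <- nchar(a) + nchar(b)
  if (n == 0L) return(100L)
  oracle_round(200 * oracle_match_total(a, b) / n)
}

# Window-enumeration partial ratio on normalized strings.
oracle_partial <- function(a, b) {
  if (nchar(a) > nchar(b) || (nchar(a) == nchar(b) && a > b)) {
    tmp <- a; a <- b; b <- tmp
  }
  ns <- nchar(a); nl <- nchar(b)
  if (ns == 0L) return(if (nl == 0L) 100L else 0L)
  raw <- vapply(seq_len(nl - ns + 1L), function(s) {
    200 * oracle_match_total(a, substr(b, s, s + ns - 1L)) / (2 * ns)
  }, numeric(1))
  raw <- c(raw, 200 * oracle_match_total(a, b) / (ns + nl))
  oracle_round(max(raw))
}

oracle_normalize_sort <- function(s) {
  s <- tolower(s)
  s <- gsub("[^a-z0-9]", " ", s)
  tok <- strsplit(s, " +")[[1]]
  tok <- tok[nzchar(tok)]
  paste(sort(tok, method = "radix"), collapse = " ")
}

oracle_ptsr <- function(a, b) {
  oracle_partial(oracle_normalize_sort(a), oracle_normalize_sort(b))
}

# --- sift oracle ------------------------------------------------------

# Literal evaluation of the five-filter cascade for one product, plain
# loops, one food at a time.
oracle_run_sift <- function(product, reference, params,
                            factors = energy_factors(), blocking = TRUE) {
  share <- function(g, fct, e) 100 * g * fct / e
  survivors <- character(0)
  for (k in seq_len(nrow(reference))) {
    food <- reference[k, ]
    if (blocking && food$blocking_group != product$blocking_group) next
    ok <- TRUE
    if (is.finite(params$macro_threshold)) {
      for (nm in c("carb", "protein", "fat")) {
        col <- paste0(nm, "_g")
        d <- abs(share(product[[col]], factors[[nm]], product$energy_kcal) -
                 share(food[[col]], factors[[nm]], food$energy_kcal))
        if (is.na(d) || d >= params$macro_threshold) ok <- FALSE
      }
    }
    if (is.finite(params$secondary_threshold)) {
      for (nm in c("fiber", "satfat", "sugar")) {
        col <- paste0(nm, "_g")
        d <- abs(share(product[[col]], factors[[nm]], product$energy_kcal) -
                 share(food[[col]], factors[[nm]], food$energy_kcal))
        if (is.na(d) || d >= params$secondary_threshold) ok <- FALSE
      }
    }
    if (is.finite(params$sodium_threshold) && product$sodium_mg > 0) {
      d <- abs(product$sodium_mg - food$sodium_mg) / product$sodium_mg
      if (is.na(d) || d >= params$sodium_threshold) ok <- FALSE
    }
    if (ok && params$use_min_fuzzy) {
      if (partial_token_sort_ratio(product$name, food$name) < params$min_fuzzy_score) {
        ok <- FALSE
      }
    }
    if (ok) survivors <- c(survivors, food$food_id)
  }
  if (params$use_fuzzy_optimization && length(survivors)) {
    pool <- reference[reference$food_id %in% survivors, , drop = FALSE]
    scores <- vapply(seq_len(nrow(pool)), function(i) {
      partial_token_sort_ratio(product$name, pool$name[i])
    }, integer(1))
    survivors <- pool$food_id[scores == max(scores)]
  }
  sort(survivors)
}

# Random small linkage instance for oracle/property suites.
random_instance <- function(n_foods = sample(0:20, 1), seed_names = NULL) {
  words <- c("oat", "bran", "milk", "cocoa", "berry", "nut", "rice",
             "corn", "soy", "cream", "dark", "light")
  mkname <- function() paste(sample(words, sample(1:3, 1), TRUE), collapse = " ")
  mkprof <- function(allow_na = FALSE) {
    carb <- runif(1, 0, 80); protein <- runif(1, 0, 30); fat <- runif(1, 0, 40)
    out <- list(
      energy_kcal = 4 * carb + 4 * protein + 9 * fat + runif(1, 5, 50),
      carb_g = carb, protein_g = protein, fat_g = fat,
      satfat_g = fat * runif(1), sugar_g = carb * runif(1),
      fiber_g = carb * runif(1, 0, 0.3),
      sodium_mg = if (runif(1) < 0.15) 0 else runif(1, 1, 800)
    )
    if (allow_na && runif(1) < 0.1) {
      out[[sample(c("satfat_g", "sugar_g", "fiber_g", "sodium_mg"), 1)]] <- NA_real_
    }
    out
  }
  product <- make_product(product_id = "P1",
                          blocking_group = sample(c("A", "B"), 1),
                          name = mkname())
  prof <- mkprof()
  for (col in names(prof)) product[[col]] <- prof[[col]]
  foods <- lapply(seq_len(n_foods), function(i) {
    fd <- make_food(food_id = sprintf("F%02d", i), name = mkname(),
                    blocking_group = sample(c("A", "B"), 1))
    prof <- mkprof(allow_na = TRUE)
    for (col in names(prof)) fd[[col]] <- prof[[col]]
    fd
  })
  reference <- if (n_foods) dplyr::bind_rows(foods) else make_food()[0, ]
  list(product = product, reference = reference)
}

random_params <- function() {
  sift_params(
    name = "rand",
    macro_threshold = sample(c(5, 10, 20, 40, 60, Inf), 1),
    secondary_threshold = sample(c(5, 10, 20, 40, 60, Inf), 1),
    sodium_threshold = sample(c(0.1, 0.25, 0.5, 1, Inf), 1),
    min_fuzzy_score = sample(c(0, 30, 50, 80), 1),
    use_min_fuzzy = runif(1) < 0.4,
    use_fuzzy_optimization = runif(1) < 0.5
  )
}

random_norm_string <- function(max_len = 12, alphabet = c("a", "b", "c", " ")) {
  len <- sample(0:max_len, 1)
  s <- paste(sample(alphabet, len, replace = TRUE), collapse = "")
  normalize_text(s)
}
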