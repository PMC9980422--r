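#' Sift parameters
#'
#' One "sift" is a pass of the five-filter cascade over a product's
#' candidate pool under a named parameter set: a shared threshold for the
#' three macronutrient share differences (carbohydrate, protein, total
#' fat), a shared threshold for the three secondary share differences
#' (fiber, saturated fat, sugar), a threshold for the relative sodium
#' difference, an optional minimum fuzzy score, and an optional
#' fuzzy-match optimization step that keeps only the top-scoring
#' candidates. `Inf` (spelled `"inf"` in YAML/JSON configs) disables a
#' threshold.
#'
#' @param name Sift label, recorded in each candidate's provenance.
#' @param macro_threshold Percentage points, or `Inf`.
#' @param secondary_threshold Percentage points, or `Inf`.
#' @param sodium_threshold Fraction (e.g. `0.5` = 50%), or `Inf`.
#' @param min_fuzzy_score Integer 0-100, used when `use_min_fuzzy`.
#' @param use_min_fuzzy Apply the minimum-fuzzy-score filter?
#' @param use_fuzzy_optimization Apply the top-fuzzy-score filter?
#' @return An object of class `sift_params`.
#' @export
sift_params <- function(name, macro_threshold, secondary_threshold,
                        sodium_threshold, min_fuzzy_score = 0,
                        use_min_fuzzy = FALSE, use_fuzzy_optimization = TRUE) {
  thr <- c(macro_threshold, secondary_threshold, sodium_threshold)
  if (any(is.na(thr)) || any(thr < 0)) {
    abort_config("Thresholds must be >= 0 (use Inf for no maximum).")
  }
  if (is.na(min_fuzzy_score) || min_fuzzy_score < 0 || min_fuzzy_score > 100) {
    abort_config("`min_fuzzy_score` must be in [0, 100].")
  }
  structure(
    list(
      name = as.character(name),
      macro_threshold = as.numeric(macro_threshold),
      secondary_threshold = as.numeric(secondary_threshold),
      sodium_threshold = as.numeric(sodium_threshold),
      min_fuzzy_score = as.numeric(min_fuzzy_score),
      use_min_fuzzy = isTRUE(use_min_fuzzy),
      use_fuzzy_optimization = isTRUE(use_fuzzy_optimization)
    ),
    class = "sift_params"
  )
}

#' @export
print.sift_params <- function(x, ...) {
  fmt <- function(v) if (is.infinite(v)) "inf" else format(v)
  cat(sprintf(
    "<sift_params> %s: macro < %s pp, secondary < %s pp, sodium < %s%s%s\n",
    x$name, fmt(x$macro_threshold), fmt(x$secondary_threshold),
    fmt(x$sodium_threshold),
    if (x$use_min_fuzzy) sprintf(", min fuzzy %g", x$min_fuzzy_score) else "",
    if (x$use_fuzzy_optimization) ", fuzzy optimization" else ""
  ))
  invisible(x)
}

#' Shipped sift presets
#'
#' The four standard parameter sets, from tightest to loosest:
#' \describe{
#'   \item{first}{macro 20 pp, secondary 10 pp, sodium 0.5; fuzzy
#'     optimization on.}
#'   \item{first_plus}{macro 60 pp, secondary 60 pp, sodium 0.5; minimum
#'     fuzzy score 50, no fuzzy optimization. Used to augment products
#'     that drew a single suggestion from `first`.}
#'   \item{second}{macro 40 pp, secondary 40 pp, sodium 0.5; fuzzy
#'     optimization on.}
#'   \item{third}{all nutrient thresholds disabled; fuzzy optimization
#'     on, so the top fuzzy scorers of the blocking pool survive.}
#' }
#'
#' @return Named list of [sift_params()] objects.
#' @export
sift_presets <- function() {
  list(
    first = sift_params("first", 20, 10, 0.5,
                        use_fuzzy_optimization = TRUE),
    first_plus = sift_params("first_plus", 60, 60, 0.5,
                             min_fuzzy_score = 50, use_min_fuzzy = TRUE,
                             use_fuzzy_optimization = FALSE),
    second = sift_params("second", 40, 40, 0.5,
                         use_fuzzy_optimization = TRUE),
    third = sift_params("third", Inf, Inf, Inf,
                        use_fuzzy_optimization = TRUE)
  )
}

#' Candidate pool of a product
#'
#' The initial candidate list: all reference foods sharing the product's
#' blocking group (the category-blocking analogue of a classic
#' record-linkage blocking key). With `blocking = FALSE` the whole
#' reference table is returned. An unknown group yields an empty pool
#' with a warning, not an error.
#'
#' @param product One-row product tibble.
#' @param reference Reference food tibble.
#' @param blocking Restrict to the shared blocking group?
#' @return Subset of `reference`.
#' @export
candidate_pool <- function(product, reference, blocking = TRUE) {
  if (!blocking) return(reference)
  pool <- reference[reference$blocking_group == product$blocking_group, , drop = FALSE]
  if (nrow(pool) == 0L) {
    rlang::warn(sprintf(
      "Blocking group \"%s\" of product %s has no reference foods.",
      product$blocking_group, product$product_id
    ))
  }
  pool
}

# Shared helper: keep pool rows whose differences for `nuts` all fall
# below `threshold` (strict by default). Missing food-side values fail a
# binding filter; an Inf threshold keeps everything.
filter_share_threshold <- function(product, pool, threshold, nuts, factors,
                                   strict = TRUE) {
  if (is.infinite(threshold) || nrow(pool) == 0L) return(pool)
  d <- difference_vector(product, pool, factors)
  keep <- rep(TRUE, nrow(pool))
  for (col in nuts) {
    ok <- if (strict) d[[col]] < threshold else d[[col]] <= threshold
    keep <- keep & !is.na(d[[col]]) & ok
  }
  pool[keep, , drop = FALSE]
}

#' Filter 1: macronutrient share thresholds
#'
#' Keeps foods whose carbohydrate, protein and total-fat
#' percent-of-calories differences from the product are all strictly
#' below `macro_threshold` (all three conditions simultaneously).
#'
#' @param product One-row eligible product tibble.
#' @param pool Candidate reference foods.
#' @param macro_threshold Percentage points, or `Inf` for no maximum.
#' @param factors An [energy_factors()] vector.
#' @param strict Use strict `<` (default) or `<=`.
#' @return Filtered pool.
#' @export
filter_macros <- function(product, pool, macro_threshold,
                          factors = energy_factors(), strict = TRUE) {
  filter_share_threshold(product, pool, macro_threshold,
                         c("d_carb_pp", "d_prot_pp", "d_fat_pp"),
                         factors, strict)
}

#' Filter 2: secondary nutrient share thresholds
#'
#' As [filter_macros()] over fiber, saturated fat and sugar.
#'
#' @inheritParams filter_macros
#' @param secondary_threshold Percentage points, or `Inf`.
#' @return Filtered pool.
#' @export
filter_secondary <- function(product, pool, secondary_threshold,
                             factors = energy_factors(), strict = TRUE) {
  filter_share_threshold(product, pool, secondary_threshold,
                         c("d_fiber_pp", "d_satfat_pp", "d_sugar_pp"),
                         factors, strict)
}

#' Filter 3: relative sodium threshold
#'
#' Applies only when the product's sodium is strictly positive: keeps
#' foods whose relative sodium difference is strictly below
#' `sodium_threshold`. Zero-sodium products pass the pool through
#' unchanged.
#'
#' @inheritParams filter_macros
#' @param sodium_threshold Fraction, or `Inf`.
#' @return Filtered pool.
#' @export
filter_sodium <- function(product, pool, sodium_threshold, strict = TRUE) {
  if (is.infinite(sodium_threshold) || nrow(pool) == 0L) return(pool)
  sod_p <- product$sodium_mg
  if (is.na(sod_p)) {
    abort_domain("Product sodium is missing but a finite sodium threshold is set.")
  }
  if (sod_p == 0) return(pool)
  rel <- abs(sod_p - pool$sodium_mg) / sod_p
  ok <- if (strict) rel < sodium_threshold else rel <= sodium_threshold
  pool[!is.na(rel) & ok, , drop = FALSE]
}

#' Filter 4: minimum fuzzy score
#'
#' Keeps foods whose [partial_token_sort_ratio()] with the product's name
#' meets or exceeds `min_score`. The meets-or-exceeds reading admits a
#' candidate scoring exactly the printed threshold; set
#' `inclusive = FALSE` for strictly-greater.
#'
#' @inheritParams filter_macros
#' @param min_score Integer 0-100.
#' @param inclusive Keep scores equal to `min_score`?
#' @return Filtered pool.
#' @export
filter_min_fuzzy <- function(product, pool, min_score, inclusive = TRUE) {
  if (nrow(pool) == 0L) return(pool)
  score <- partial_token_sort_ratio(product$name, pool$name)
  keep <- if (inclusive) score >= min_score else score > min_score
  pool[keep, , drop = FALSE]
}

#' Filter 5: fuzzy-match optimization
#'
#' Keeps every food achieving the maximum fuzzy score against the
#' product among the foods remaining from the previous filter (ties all
#' kept). An empty pool stays empty. Unlike filters 1-4 this filter is
#' not monotone in the pool, so its position at the end of the cascade is
#' normative.
#'
#' @inheritParams filter_macros
#' @return Filtered pool.
#' @export
filter_fuzzy_optimization <- function(product, pool) {
  if (nrow(pool) == 0L) return(pool)
  score <- partial_token_sort_ratio(product$name, pool$name)
  pool[score == max(score), , drop = FALSE]
}

#' Run one sift for one product
#'
#' Composes the cascade in its fixed order: blocking-group pool, then
#' filters 1 (macro shares), 2 (secondary shares), 3 (sodium), 4
#' (minimum fuzzy score, if enabled), 5 (fuzzy optimization, if
#' enabled). Each surviving food is materialized as a candidate row with
#' its full difference vector, maximal nutritional difference, fuzzy
#' score, and the sift's name as provenance.
#'
#' @param product One-row eligible product tibble.
#' @param reference Reference food tibble.
#' @param params A [sift_params()] object.
#' @param factors An [energy_factors()] vector.
#' @param blocking Restrict candidates to the shared blocking group?
#' @param strict Strict (`<`) nutrient threshold comparison?
#' @param fuzzy_inclusive Meets-or-exceeds minimum fuzzy comparison?
#' @param sodium_in_ranking Include sodium in `max_diff` (see
#'   [max_nutritional_difference()])?
#' @return A candidate tibble: `product_id`, `food_id`, `food_name`, the
#'   difference columns, `max_diff`, `fuzzy_score`, `sift_name`.
#' @export
run_sift <- function(product, reference, params,
                     factors = energy_factors(), blocking = TRUE,
                     strict = TRUE, fuzzy_inclusive = TRUE,
                     sodium_in_ranking = TRUE) {
  if (nrow(product) != 1L) abort_usage("`product` must be a single row.")
  if ("eligible" %in% names(product) && !isTRUE(product[["eligible"]])) {
    abort_usage(sprintf(
      "Product %s is ineligible for the algorithm (route it to manual matching).",
      product$product_id
    ))
  }
  pool <- candidate_pool(product, reference, blocking)
  pool <- filter_macros(product, pool, params$macro_threshold, factors, strict)
  pool <- filter_secondary(product, pool, params$secondary_threshold, factors, strict)
  pool <- filter_sodium(product, pool, params$sodium_threshold, strict)
  if (params$use_min_fuzzy) {
    pool <- filter_min_fuzzy(product, pool, params$min_fuzzy_score, fuzzy_inclusive)
  }
  if (params$use_fuzzy_optimization) {
    pool <- filter_fuzzy_optimization(product, pool)
  }
  materialize_candidates(product, pool, params$name, factors, sodium_in_ranking)
}

materialize_candidates <- function(product, pool, sift_name, factors,
                                   sodium_in_ranking = TRUE) {
  if (nrow(pool) == 0L) return(empty_candidates())
  d <- difference_vector(product, pool, factors)
  tibble(
    product_id = product$product_id,
    food_id = pool$food_id,
    food_name = pool$name,
    d_carb_pp = d$d_carb_pp,
    d_prot_pp = d$d_prot_pp,
    d_fat_pp = d$d_fat_pp,
    d_satfat_pp = d$d_satfat_pp,
    d_sugar_pp = d$d_sugar_pp,
    d_fiber_pp = d$d_fiber_pp,
    d_sodium_rel = d$d_sodium_rel,
    sodium_skipped = d$sodium_skipped,
    max_diff = max_nutritional_difference(d, sodium_in_ranking),
    fuzzy_score = partial_token_sort_ratio(product$name, pool$name),
    sift_name = sift_name
  )
}

empty_candidates <- function() {
  tibble(
    product_id = character(0), food_id = character(0), food_name = character(0),
    d_carb_pp = numeric(0), d_prot_pp = numeric(0), d_fat_pp = numeric(0),
    d_satfat_pp = numeric(0), d_sugar_pp = numeric(0), d_fiber_pp = numeric(0),
    d_sodium_rel = numeric(0), sodium_skipped = logical(0),
    max_diff = numeric(0), fuzzy_score = integer(0), sift_name = character(0)
  )
}
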