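#' Energy conversion factors
#'
#' kcal-per-gram factors used to express a nutrient's content as a share
#' of total energy. Defaults are Atwater-style: carbohydrate 4, protein
#' 4, total fat 9, saturated fat 9, sugar 4, fiber 2 kcal/g. All factors
#' must be strictly positive. Sodium carries no energy and is compared on
#' a relative scale instead (see [relative_sodium_difference()]).
#'
#' @param carb,protein,fat,satfat,sugar,fiber kcal per gram.
#' @return Named numeric vector of class `energy_factors`.
#' @export
energy_factors <- function(carb = 4, protein = 4, fat = 9,
                           satfat = 9, sugar = 4, fiber = 2) {
  f <- c(carb = carb, protein = protein, fat = fat,
         satfat = satfat, sugar = sugar, fiber = fiber)
  if (any(!is.finite(f)) || any(f <= 0)) {
    abort_validation("All energy factors must be finite and > 0.")
  }
  structure(f, class = c("energy_factors", "numeric"))
}

# caloric nutrient -> profile column
CALORIC_COLS <- c(
  carb = "carb_g", protein = "protein_g", fat = "fat_g",
  satfat = "satfat_g", sugar = "sugar_g", fiber = "fiber_g"
)

#' Nutrient content as a percentage of calories
#'
#' `100 * nutrient_g * factor / energy_kcal`. Expressing nutrient content
#' as a share of energy makes comparisons robust across products with
#' very different caloric densities: an absolute gram difference is
#' meaningless between a 500 kcal snack and a 15 kcal drink, and a
#' relative gram difference explodes for near-zero contents. The result
#' is not clamped and can exceed 100 (rounded label data, fiber
#' conventions).
#'
#' @param nutrient_g Grams of the nutrient (non-negative).
#' @param nutrient One of `"carb"`, `"protein"`, `"fat"`, `"satfat"`,
#'   `"sugar"`, `"fiber"`.
#' @param energy_kcal Total energy, must be > 0.
#' @param factors An [energy_factors()] vector.
#' @return Percent of calories contributed by the nutrient.
#' @examples
#' proportion_of_calories(7.5, "carb", 100) # 30
#' @export
proportion_of_calories <- function(nutrient_g, nutrient, energy_kcal,
                                   factors = energy_factors()) {
  nutrient <- match.arg(nutrient, names(CALORIC_COLS))
  if (any(is.na(energy_kcal)) || any(energy_kcal <= 0)) {
    abort_domain("`energy_kcal` must be > 0 (zero-energy records are screened out).")
  }
  if (any(!is.na(nutrient_g) & nutrient_g < 0)) {
    abort_validation("`nutrient_g` must be non-negative.")
  }
  100 * nutrient_g * factors[[nutrient]] / energy_kcal
}

#' Absolute difference of two percent-of-calories shares
#'
#' @param p_a,p_b Percent-of-calories values.
#' @return `|p_a - p_b|` in percentage points.
#' @examples
#' proportion_difference(30, 20) # 10
#' @export
proportion_difference <- function(p_a, p_b) {
  abs(p_a - p_b)
}

#' Relative sodium difference
#'
#' `|sodium_product - sodium_food| / sodium_product`, defined only when
#' the product's sodium is strictly positive; callers must skip the
#' sodium filter for zero-sodium products rather than evaluate this.
#'
#' @param sodium_product_mg Product sodium in mg, must be > 0.
#' @param sodium_food_mg Reference-food sodium in mg.
#' @return Absolute relative difference as a fraction (can exceed 1 when
#'   the food's sodium is more than twice the product's).
#' @export
relative_sodium_difference <- function(sodium_product_mg, sodium_food_mg) {
  if (any(is.na(sodium_product_mg)) || any(sodium_product_mg <= 0)) {
    abort_domain("Product sodium must be > 0; skip the sodium filter otherwise.")
  }
  abs(sodium_product_mg - sodium_food_mg) / sodium_product_mg
}

# Percent-of-calories shares for all six caloric nutrients of a profile
# tibble/row set. Returns a data.frame with columns named by nutrient.
nutrient_shares <- function(profile, factors = energy_factors()) {
  out <- lapply(names(CALORIC_COLS), function(nut) {
    100 * profile[[CALORIC_COLS[[nut]]]] * factors[[nut]] / profile$energy_kcal
  })
  names(out) <- names(CALORIC_COLS)
  as.data.frame(out, optional = TRUE)
}

#' Per-candidate nutrient difference vector
#'
#' For one product against one or more reference foods, computes the six
#' percent-of-calories differences (percentage points, absolute) and the
#' relative sodium difference (fraction, absolute). When the product's
#' sodium is zero the sodium term is skipped (`sodium_skipped = TRUE`,
#' `d_sodium_rel = NA`), mirroring the sodium filter's applicability
#' rule. A missing food-side field yields `NA` in the corresponding
#' difference.
#'
#' @param product One-row product tibble with energy > 0.
#' @param foods Reference food tibble (one row per candidate), all with
#'   energy > 0.
#' @param factors An [energy_factors()] vector.
#' @return A tibble with columns `d_carb_pp`, `d_prot_pp`, `d_fat_pp`,
#'   `d_satfat_pp`, `d_sugar_pp`, `d_fiber_pp`, `d_sodium_rel`,
#'   `sodium_skipped`, aligned with `foods`.
#' @export
difference_vector <- function(product, foods, factors = energy_factors()) {
  if (nrow(product) != 1L) abort_usage("`product` must be a single row.")
  if (is.na(product$energy_kcal) || product$energy_kcal <= 0) {
    abort_domain("Product energy must be > 0.")
  }
  if (nrow(foods) && any(is.na(foods$energy_kcal) | foods$energy_kcal <= 0)) {
    abort_domain("All candidate foods must have energy > 0.")
  }
  sp <- nutrient_shares(product, factors)
  sf <- nutrient_shares(foods, factors)
  sodium_skipped <- is.na(product$sodium_mg) || product$sodium_mg == 0
  d_sodium <- if (sodium_skipped || nrow(foods) == 0L) {
    rep(NA_real_, nrow(foods))
  } else {
    abs(product$sodium_mg - foods$sodium_mg) / product$sodium_mg
  }
  tibble(
    d_carb_pp   = abs(sp$carb - sf$carb),
    d_prot_pp   = abs(sp$protein - sf$protein),
    d_fat_pp    = abs(sp$fat - sf$fat),
    d_satfat_pp = abs(sp$satfat - sf$satfat),
    d_sugar_pp  = abs(sp$sugar - sf$sugar),
    d_fiber_pp  = abs(sp$fiber - sf$fiber),
    d_sodium_rel = d_sodium,
    sodium_skipped = rep(sodium_skipped, nrow(foods))
  )
}

DIFF_PP_COLS <- c("d_carb_pp", "d_prot_pp", "d_fat_pp",
                  "d_satfat_pp", "d_sugar_pp", "d_fiber_pp")

#' Maximal nutritional difference of a candidate pair
#'
#' The largest entry of a difference vector, on a common percent scale:
#' the six percentage-point differences and, unless skipped or excluded,
#' the relative sodium difference times 100. Candidates are ranked
#' ascending by this quantity ("smallest nutritional error first").
#' Mixing percentage points with relative percent is the most literal
#' reading of taking "the largest" across the three filter families; set
#' `sodium_in_ranking = FALSE` to rank on the caloric nutrients only.
#'
#' @param diffs A difference-vector tibble from [difference_vector()].
#' @param sodium_in_ranking Include the sodium term in the max?
#' @return Numeric vector of maxima (percent scale), `NA` if every entry
#'   of a row is missing.
#' @export
max_nutritional_difference <- function(diffs, sodium_in_ranking = TRUE) {
  if (nrow(diffs) == 0L) return(numeric(0))
  m <- as.matrix(diffs[DIFF_PP_COLS])
  if (sodium_in_ranking) {
    sod <- ifelse(diffs$sodium_skipped, NA_real_, diffs$d_sodium_rel * 100)
    m <- cbind(m, sod)
  }
  apply(m, 1, function(row) {
    if (all(is.na(row))) NA_real_ else max(row, na.rm = TRUE)
  })
}

#' Rank a product's candidate matches
#'
#' Orders the candidate table of a single product ascending by
#' `max_diff`, breaking ties by `food_id` (byte order) so the ranking is
#' deterministic. Missing `max_diff` sorts last.
#'
#' @param candidates Candidate tibble (as produced by [run_sift()]) all
#'   belonging to one product.
#' @return The same tibble, reordered, with a `rank` column added.
#' @export
rank_candidates <- function(candidates) {
  if (nrow(candidates) == 0L) {
    candidates$rank <- integer(0)
    return(candidates)
  }
  if (length(unique(candidates$product_id)) > 1L) {
    abort_usage("`rank_candidates()` expects candidates of a single product.")
  }
  ord <- order(is.na(candidates$max_diff), candidates$max_diff,
               candidates$food_id, method = "radix")
  out <- candidates[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out
}
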