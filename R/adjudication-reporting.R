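#' Rater decision bookkeeping
#'
#' Expert validation happens in two stages. In the *algorithm* stage a
#' rater either selects one of the algorithm's suggested foods for a
#' product or refuses all of them (verdict `"REFUSE"`), sending the
#' product to manual selection. In the *manual* stage a rater selects
#' any reference food or declares the product `"UNMATCHABLE"`. A
#' decision log is a tibble with columns `product_id`, `rater_id`,
#' `stage` (`"algorithm"` or `"manual"`), `verdict`, and optionally
#' `resolution_round` (1 = the two independent raters; later rounds
#' record tie-break/consensus decisions and are excluded from the
#' agreement rates).
#'
#' @param path CSV file with the columns above.
#' @return Decision tibble.
#' @export
read_decisions <- function(path) {
  d <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE, show_col_types = FALSE)
  need <- c("product_id", "rater_id", "stage", "verdict")
  missing <- setdiff(need, names(d))
  if (length(missing)) {
    abort_schema(sprintf("Decision log is missing column(s): %s.",
                         paste(missing, collapse = ", ")))
  }
  if (!"resolution_round" %in% names(d)) d$resolution_round <- "1"
  d$resolution_round <- as.integer(d$resolution_round)
  d
}

#' Sentinel verdicts
#'
#' @return The refusal sentinel (`"REFUSE"`, algorithm stage) or the
#'   unmatchable sentinel (`"UNMATCHABLE"`, manual stage).
#' @export
#' @name verdict_sentinels
REFUSE <- "REFUSE"

#' @rdname verdict_sentinels
#' @export
UNMATCHABLE <- "UNMATCHABLE"

# Spread a two-rater decision log into per-product verdict pairs.
decision_pairs <- function(decisions, stage, raters = NULL) {
  d <- decisions[decisions$stage == stage, , drop = FALSE]
  if ("resolution_round" %in% names(d)) {
    d <- d[is.na(d$resolution_round) | d$resolution_round == 1L, , drop = FALSE]
  }
  raters <- raters %||% sort(unique(d$rater_id))
  if (length(raters) != 2L) {
    abort_validation("Agreement rates are defined for exactly two raters; pass `raters`.")
  }
  d <- d[d$rater_id %in% raters, , drop = FALSE]
  if (nrow(d) == 0L) abort_validation("No decisions for the requested stage/raters.")
  wide <- tidyr::pivot_wider(
    d[c("product_id", "rater_id", "verdict")],
    names_from = "rater_id", values_from = "verdict",
    values_fn = function(x) if (length(x) > 1L) NA_character_ else x
  )
  dup <- table(d$product_id, d$rater_id)
  if (any(dup > 1L)) {
    abort_validation("Each product must have exactly one decision per rater.")
  }
  v1 <- wide[[raters[1]]]
  v2 <- wide[[raters[2]]]
  if (anyNA(v1) || anyNA(v2)) {
    abort_validation("Each product must have exactly one decision per rater.")
  }
  tibble(product_id = wide$product_id, v1 = v1, v2 = v2)
}

#' Inter-rater agreement on algorithm-stage selection
#'
#' Percent of products on which two raters returned an identical verdict
#' in the algorithm stage — both chose the same suggested food, or both
#' refused every suggestion.
#'
#' @param decisions Decision tibble (see [read_decisions()]).
#' @param raters Optional character vector naming the two raters; by
#'   default the log must contain exactly two.
#' @return Agreement rate in percent.
#' @export
agreement_selection <- function(decisions, raters = NULL) {
  p <- decision_pairs(decisions, "algorithm", raters)
  100 * mean(p$v1 == p$v2)
}

#' Inter-rater agreement on whether manual selection is needed
#'
#' Percent of products on which two raters agreed on the refuse-vs-select
#' dichotomy: both refused the algorithm's options, or both selected
#' *some* food (not necessarily the same one). Identical verdicts imply
#' dichotomy agreement, so this rate is never below
#' [agreement_selection()] on the same log.
#'
#' @inheritParams agreement_selection
#' @return Agreement rate in percent.
#' @export
agreement_manual_needed <- function(decisions, raters = NULL) {
  p <- decision_pairs(decisions, "algorithm", raters)
  100 * mean((p$v1 == REFUSE) == (p$v2 == REFUSE))
}

#' Inter-rater agreement on manual selection
#'
#' Percent of manually-managed products on which two raters selected the
#' same reference food (declaring the product unmatchable counts as a
#' verdict, so two `"UNMATCHABLE"`s agree).
#'
#' @inheritParams agreement_selection
#' @return Agreement rate in percent.
#' @export
agreement_manual_selection <- function(decisions, raters = NULL) {
  p <- decision_pairs(decisions, "manual", raters)
  100 * mean(p$v1 == p$v2)
}

#' Category rollup
#'
#' Collapses fine product subcategories into broader reporting
#' categories ("intercategories"). The mapping must be total over the
#' subcategories it is applied to.
#'
#' @param mapping Tibble/data.frame with columns `subcategory` and
#'   `category`, or a named character vector `subcategory -> category`,
#'   or `NULL` (identity: each subcategory is its own category).
#' @param subcategories Character vector the rollup will be applied to.
#' @return Named character vector `subcategory -> category`.
#' @export
category_rollup <- function(mapping, subcategories) {
  if (is.null(mapping)) {
    return(stats::setNames(subcategories, subcategories))
  }
  if (is.data.frame(mapping)) {
    mapping <- stats::setNames(as.character(mapping$category),
                               as.character(mapping$subcategory))
  }
  if (anyDuplicated(names(mapping))) {
    abort_validation("Rollup maps a subcategory to more than one category.")
  }
  missing <- setdiff(unique(subcategories), names(mapping))
  if (length(missing)) {
    abort_validation(sprintf(
      "Rollup is not total; unmapped subcategories: %s.",
      paste(missing, collapse = ", ")
    ))
  }
  mapping
}

#' Algorithm accuracy by category and match level
#'
#' A product with at least one algorithm suggestion counts as accurately
#' matched when its final adjudicated verdict selects one of those
#' suggestions (a `"REFUSE"` verdict counts as inaccurate). Accuracy is
#' the number of accurately matched products divided by the number of
#' products with at least one suggestion, reported per category, per
#' match level (1 / many), and overall. An adjudicated food that is not
#' among the product's suggestions raises an integrity error.
#'
#' @param report A `match_report` from [run_schedule()].
#' @param adjudications Tibble with `product_id` and `verdict` (a food id
#'   or `"REFUSE"`) covering every product at level 1 or many.
#' @param rollup Passed to [category_rollup()].
#' @return Tibble with columns `category`, `level` (`"1"`, `"many"`,
#'   `"all"`), `n_products`, `n_accurate`, `pct_accurate` (1 decimal,
#'   half-up; `NA` where no products).
#' @export
algorithm_accuracy <- function(report, adjudications, rollup = NULL) {
  prods <- report$products
  prods <- prods[!is.na(prods$level) & prods$level %in% c("1", "many"), , drop = FALSE]
  miss <- setdiff(prods$product_id, adjudications$product_id)
  if (length(miss)) {
    abort_validation(sprintf("Missing adjudication for product(s): %s.",
                             paste(miss, collapse = ", ")))
  }
  adj <- adjudications[match(prods$product_id, adjudications$product_id), , drop = FALSE]
  sugg <- split(report$candidates$food_id, report$candidates$product_id)
  accurate <- vapply(seq_len(nrow(prods)), function(i) {
    v <- adj$verdict[i]
    if (v == REFUSE) return(FALSE)
    if (!v %in% (sugg[[prods$product_id[i]]] %||% character(0))) {
      abort_integrity(sprintf(
        "Adjudicated food %s is not among the suggestions of product %s.",
        v, prods$product_id[i]
      ))
    }
    TRUE
  }, logical(1))
  map <- category_rollup(rollup, prods$subcategory)
  base <- tibble(
    category = unname(map[prods$subcategory]),
    level = as.character(prods$level),
    accurate = accurate
  )
  summarize_acc <- function(df, cat_label, lvl_label) {
    tibble(category = cat_label, level = lvl_label,
           n_products = nrow(df), n_accurate = sum(df$accurate),
           pct_accurate = if (nrow(df)) round_half_up(100 * mean(df$accurate), 1) else NA_real_)
  }
  out <- list()
  for (cat in sort(unique(base$category))) {
    for (lvl in c("1", "many", "all")) {
      df <- base[base$category == cat & (lvl == "all" | base$level == lvl), , drop = FALSE]
      out[[length(out) + 1L]] <- summarize_acc(df, cat, lvl)
    }
  }
  for (lvl in c("1", "many", "all")) {
    df <- base[lvl == "all" | base$level == lvl, , drop = FALSE]
    out[[length(out) + 1L]] <- summarize_acc(df, "Overall", lvl)
  }
  dplyr::bind_rows(out)
}

#' Overall process accuracy by category
#'
#' After both the algorithm-aided and the manual stages, every product
#' has a terminal outcome: matched to some reference food, or deemed
#' unmatchable. Process accuracy per category is the percent matched.
#'
#' @param products Product tibble (the full table, including products
#'   routed directly to manual matching).
#' @param outcomes Tibble with `product_id` and `outcome` (`"matched"` or
#'   `"unmatchable"`) covering every product.
#' @param rollup Passed to [category_rollup()].
#' @return Tibble with `category`, `n_products`, `n_matched`,
#'   `n_unmatchable`, `pct_matched` (1 decimal, half-up), ending with a
#'   `Total` row.
#' @export
process_accuracy <- function(products, outcomes, rollup = NULL) {
  miss <- setdiff(products$product_id, outcomes$product_id)
  if (length(miss)) {
    abort_validation(sprintf("Missing terminal outcome for product(s): %s.",
                             paste(miss, collapse = ", ")))
  }
  oc <- outcomes$outcome[match(products$product_id, outcomes$product_id)]
  if (!all(oc %in% c("matched", "unmatchable"))) {
    abort_validation("Outcomes must be \"matched\" or \"unmatchable\".")
  }
  map <- category_rollup(rollup, products$subcategory)
  base <- tibble(category = unname(map[products$subcategory]),
                 matched = oc == "matched")
  row_for <- function(df, label) {
    tibble(category = label, n_products = nrow(df),
           n_matched = sum(df$matched), n_unmatchable = sum(!df$matched),
           pct_matched = if (nrow(df)) round_half_up(100 * mean(df$matched), 1) else NA_real_)
  }
  out <- lapply(sort(unique(base$category)),
                function(cat) row_for(base[base$category == cat, ], cat))
  dplyr::bind_rows(c(out, list(row_for(base, "Total"))))
}

#' Suggested-match count distribution across nutrient thresholds
#'
#' Diagnostic for threshold selection: for each value in a grid, the
#' nutrient filters (1-3 only; fuzzy matching disabled) are run for every
#' eligible product and the distribution of the square roots of the
#' per-product suggestion counts is summarized at the 0/25/50/75/100th
#' percentiles (the boxplot statistics; square roots keep large counts
#' readable). `vary = "macro"` sweeps the macronutrient threshold with
#' the secondary and sodium thresholds fixed; `vary = "sodium"` sweeps
#' the sodium threshold.
#'
#' @param dataset A [linkage_dataset()].
#' @param grid Numeric vector of thresholds to sweep (percentage points
#'   for `"macro"`, fraction for `"sodium"`; `Inf` allowed).
#' @param vary `"macro"` or `"sodium"`.
#' @param macro_threshold,secondary_threshold,sodium_threshold The fixed
#'   values of the parameters not being swept.
#' @param factors An [energy_factors()] vector.
#' @param blocking Restrict pools to shared blocking groups?
#' @return Tibble with one row per grid value: `threshold`,
#'   `n_products`, and `p0`, `p25`, `p50`, `p75`, `p100` of
#'   `sqrt(match count)`.
#' @export
threshold_sweep <- function(dataset, grid, vary = c("macro", "sodium"),
                            macro_threshold = 20, secondary_threshold = 40,
                            sodium_threshold = 0.5,
                            factors = energy_factors(), blocking = TRUE) {
  vary <- match.arg(vary)
  if (length(grid) == 0L) abort_usage("`grid` must be nonempty.")
  screened <- screen_eligibility(dataset$products)
  eligible <- screened$eligible
  if (nrow(eligible) == 0L) {
    return(tibble(threshold = numeric(0), n_products = integer(0),
                  p0 = numeric(0), p25 = numeric(0), p50 = numeric(0),
                  p75 = numeric(0), p100 = numeric(0)))
  }
  rows <- lapply(grid, function(g) {
    macro <- if (vary == "macro") g else macro_threshold
    sodium <- if (vary == "sodium") g else sodium_threshold
    counts <- vapply(seq_len(nrow(eligible)), function(i) {
      p <- eligible[i, , drop = FALSE]
      pool <- suppressWarnings(candidate_pool(p, dataset$reference, blocking))
      pool <- filter_macros(p, pool, macro, factors)
      pool <- filter_secondary(p, pool, secondary_threshold, factors)
      pool <- filter_sodium(p, pool, sodium)
      nrow(pool)
    }, integer(1))
    q <- stats::quantile(sqrt(counts), probs = c(0, .25, .5, .75, 1), names = FALSE)
    tibble(threshold = g, n_products = length(counts),
           p0 = q[1], p25 = q[2], p50 = q[3], p75 = q[4], p100 = q[5])
  })
  dplyr::bind_rows(rows)
}
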