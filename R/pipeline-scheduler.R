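#' Multi-sift schedule
#'
#' The routing plan across sifts. Every eligible product first runs
#' through `initial`. Products left with zero suggestions are re-run
#' through the `zero_match_chain` entries in order until they gain at
#' least one suggestion or the chain is exhausted. Products that drew
#' exactly one suggestion from the *initial* sift are re-run through the
#' `augmentation` sift; its output *replaces* the original single
#' suggestion, even when empty — which is the one route by which a
#' product with an earlier suggestion can end at level 0. Single-match
#' products of later chain sifts are final and are not augmented.
#'
#' @param initial Preset name or [sift_params()] for the first pass.
#' @param zero_match_chain Character vector of preset names (or list of
#'   [sift_params()]) applied successively to zero-match products.
#' @param augmentation Preset name or [sift_params()] applied to the
#'   initial sift's single-match products, or `NULL` to disable.
#' @param presets Named list resolving preset names; defaults to
#'   [sift_presets()].
#' @param augmentation_mode `"replace"` (the augmented set supersedes the
#'   original suggestion) or `"retain_fallback"` (an empty augmented set
#'   falls back to the original single suggestion).
#' @return An object of class `sift_schedule`.
#' @export
sift_schedule <- function(initial = "first",
                          zero_match_chain = c("second", "third"),
                          augmentation = "first_plus",
                          presets = sift_presets(),
                          augmentation_mode = c("replace", "retain_fallback")) {
  augmentation_mode <- match.arg(augmentation_mode)
  resolve <- function(x) {
    if (inherits(x, "sift_params")) return(x)
    if (is.character(x) && length(x) == 1L) {
      if (!x %in% names(presets)) {
        abort_config(sprintf("Unknown sift preset \"%s\".", x))
      }
      return(presets[[x]])
    }
    abort_config("Schedule entries must be preset names or sift_params objects.")
  }
  sched <- structure(
    list(
      initial = resolve(initial),
      zero_match_chain = lapply(zero_match_chain, resolve),
      augmentation = if (is.null(augmentation)) NULL else resolve(augmentation),
      augmentation_mode = augmentation_mode
    ),
    class = "sift_schedule"
  )
  nms <- vapply(schedule_sifts(sched), `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    abort_config("Sift names within a schedule must be unique.")
  }
  sched
}

schedule_sifts <- function(schedule) {
  c(list(schedule$initial), schedule$zero_match_chain,
    if (!is.null(schedule$augmentation)) list(schedule$augmentation))
}

#' Default schedule
#'
#' `first` initially, `second` then `third` for zero-match products, and
#' `first_plus` augmentation (replace mode) for the initial sift's
#' single-match products.
#'
#' @return A [sift_schedule()].
#' @export
default_schedule <- function() sift_schedule()

#' Profile fields a schedule actually needs
#'
#' Energy is always required (the share filters divide by it); the six
#' caloric nutrients are required when any sift in the schedule binds a
#' finite macro/secondary threshold, and sodium when any sift binds a
#' finite sodium threshold. Used to operationalize "missing key nutrient
#' information" relative to the active schedule.
#'
#' @param schedule A [sift_schedule()].
#' @return Character vector of required profile columns.
#' @export
schedule_required_fields <- function(schedule) {
  sifts <- schedule_sifts(schedule)
  fields <- "energy_kcal"
  if (any(vapply(sifts, function(s) is.finite(s$macro_threshold), logical(1)))) {
    fields <- c(fields, "carb_g", "protein_g", "fat_g")
  }
  if (any(vapply(sifts, function(s) is.finite(s$secondary_threshold), logical(1)))) {
    fields <- c(fields, "fiber_g", "satfat_g", "sugar_g")
  }
  if (any(vapply(sifts, function(s) is.finite(s$sodium_threshold), logical(1)))) {
    fields <- c(fields, "sodium_mg")
  }
  fields
}

#' Match level of a suggestion set
#'
#' @param n Suggestion count (or a candidate tibble, whose rows are
#'   counted).
#' @return `"0"`, `"1"`, or `"many"` (factor with those levels).
#' @export
match_level <- function(n) {
  if (is.data.frame(n)) n <- nrow(n)
  factor(
    dplyr::case_when(n == 0 ~ "0", n == 1 ~ "1", .default = "many"),
    levels = c("0", "1", "many")
  )
}

#' Run a sift schedule over a dataset
#'
#' Screens eligibility against the schedule's required fields, routes
#' ineligible products directly to manual matching, and runs eligible
#' products through the schedule's sifts (see [sift_schedule()] for the
#' routing rules). Final suggestion sets are ranked by
#' [rank_candidates()]. The whole pipeline is deterministic: identical
#' inputs and schedule produce identical reports.
#'
#' @param dataset A [linkage_dataset()].
#' @param schedule A [sift_schedule()].
#' @param factors An [energy_factors()] vector.
#' @param ... Comparison-mode switches forwarded to [run_sift()]
#'   (`blocking`, `strict`, `fuzzy_inclusive`, `sodium_in_ranking`).
#' @return An object of class `match_report`: list with `products` (one
#'   row per product: `route`, final `level`, `provenance`),
#'   `candidates` (one row per final product-candidate pair, ranked),
#'   `flow` (per-sift conservation table), and the `schedule`.
#' @export
run_schedule <- function(dataset, schedule = default_schedule(),
                         factors = energy_factors(), ...) {
  stopifnot(inherits(dataset, "linkage_dataset"),
            inherits(schedule, "sift_schedule"))
  screened <- screen_eligibility(dataset$products,
                                 required_fields = schedule_required_fields(schedule))
  products <- screened$products
  eligible <- screened$eligible
  reference <- dataset$reference

  sets <- stats::setNames(vector("list", nrow(eligible)), eligible$product_id)
  provenance <- stats::setNames(rep(NA_character_, nrow(eligible)),
                                eligible$product_id)
  flow <- list()

  run_pass <- function(params, ids) {
    out <- lapply(ids, function(pid) {
      suppressWarnings(run_sift(eligible[eligible$product_id == pid, , drop = FALSE],
                                reference, params, factors, ...))
    })
    stats::setNames(out, ids)
  }
  record_flow <- function(name, out_sets) {
    lv <- vapply(out_sets, nrow, integer(1))
    flow[[length(flow) + 1L]] <<- tibble(
      sift = name, entered = length(out_sets),
      out_zero = sum(lv == 0L), out_one = sum(lv == 1L), out_many = sum(lv >= 2L)
    )
  }

  # (b) initial sift
  init <- schedule$initial
  ids <- eligible$product_id
  out <- run_pass(init, ids)
  sets[ids] <- out
  provenance[ids] <- init$name
  record_flow(init$name, out)
  initial_level <- vapply(out, nrow, integer(1))
  single_after_initial <- ids[initial_level == 1L]

  # (c) zero-match chain
  zero_ids <- ids[initial_level == 0L]
  for (params in schedule$zero_match_chain) {
    if (length(zero_ids) == 0L) {
      record_flow(params$name, stats::setNames(list(), character(0)))
      next
    }
    out <- run_pass(params, zero_ids)
    record_flow(params$name, out)
    gained <- vapply(out, nrow, integer(1)) > 0L
    sets[zero_ids[gained]] <- out[gained]
    provenance[zero_ids[gained]] <- params$name
    zero_ids <- zero_ids[!gained]
  }

  # (d) augmentation of the initial sift's single-match products
  if (!is.null(schedule$augmentation)) {
    aug <- schedule$augmentation
    out <- run_pass(aug, single_after_initial)
    record_flow(aug$name, out)
    for (pid in single_after_initial) {
      if (schedule$augmentation_mode == "retain_fallback" && nrow(out[[pid]]) == 0L) next
      sets[[pid]] <- out[[pid]]
      provenance[[pid]] <- aug$name
    }
  }

  # (e) rank final sets
  sets <- lapply(sets, rank_candidates)
  candidates <- dplyr::bind_rows(sets)

  levels_final <- match_level(vapply(sets, nrow, integer(1)))
  prod_rows <- tibble(
    product_id = products$product_id,
    subcategory = products$subcategory,
    blocking_group = products$blocking_group,
    eligible = products$eligible,
    route = ifelse(products$eligible, "algorithm", "direct_manual"),
    exclusion_reason = products$exclusion_reason
  )
  elig_tbl <- tibble(
    product_id = eligible$product_id,
    level = as.character(levels_final),
    provenance = unname(provenance)
  )
  prod_rows <- dplyr::left_join(prod_rows, elig_tbl, by = "product_id")

  structure(
    list(
      products = prod_rows,
      candidates = candidates,
      flow = dplyr::bind_rows(flow),
      schedule = schedule
    ),
    class = "match_report"
  )
}

#' @export
print.match_report <- function(x, ...) {
  lv <- table(factor(x$products$level, levels = c("0", "1", "many")))
  cat(sprintf(
    "<match_report> %d products (%d direct to manual); levels: 0=%d, 1=%d, many=%d\n",
    nrow(x$products), sum(x$products$route == "direct_manual"),
    lv[["0"]], lv[["1"]], lv[["many"]]
  ))
  invisible(x)
}

#' Per-sift flow summary
#'
#' One row per executed sift with the number of products that entered it
#' and the sizes of its output level classes. Conservation holds by
#' construction: `entered = out_zero + out_one + out_many` on every row.
#'
#' @param report A `match_report` from [run_schedule()].
#' @return Tibble with columns `sift`, `entered`, `out_zero`, `out_one`,
#'   `out_many`.
#' @export
flow_summary <- function(report) {
  stopifnot(inherits(report, "match_report"))
  report$flow
}
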