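#' Synthetic linkage benchmark configuration
#'
#' Parameters of the synthetic product/reference generator. The
#' generator emulates the statistical structure of a branded-product
#' table linked to a food-composition table: reference foods with
#' category-structured nutrient profiles per 100 g, products cloned from
#' reference foods with multiplicative nutrient noise and marketing-style
#' names (corrupted food tokens plus a brand token), a fraction of
#' products with no true counterpart, and a fraction with zero energy or
#' missing fields (which real tables also contain and which the
#' eligibility screen must divert).
#'
#' Energy is recomputed from the perturbed carbohydrate/protein/fat
#' grams via the energy factors, so a relative nutrient perturbation of
#' amplitude `p` bounds every percent-of-calories share deviation by a
#' factor `(1+p)^2` of the unperturbed share (shares never exceed 100
#' when energy derives from the macros, and the fiber share tops out at
#' 50 with the default factors). That analytic bound is what makes the
#' guaranteed-recovery property provable rather than merely empirical:
#' `100 * ((1+p)^2 - 1)` below the tightest share threshold implies the
#' true food passes every nutrient filter.
#'
#' @param seed Integer seed; a fixed seed yields byte-identical output.
#' @param n_groups Number of blocking groups.
#' @param foods_per_group,products_per_group Scalar count or vector to
#'   sample from, per group.
#' @param perturbation Relative noise amplitude `p`: each nutrient of a
#'   cloned product is multiplied by an independent factor in
#'   `[1/(1+p), 1+p]` (log-uniform).
#' @param name_model List with token corruption probabilities
#'   `shuffle_prob`, `drop_prob`, `insert_prob`, `brand_prob`, and
#'   `tokens_per_food` (vector of name lengths to sample from).
#' @param unmatchable_fraction Fraction of products drawn fresh, with no
#'   true counterpart.
#' @param zero_energy_fraction,missing_field_fraction Fractions of
#'   products recorded with zero energy / one missing nutrient field.
#' @param factors An [energy_factors()] vector used to derive energy.
#' @return A `generator_config` list.
#' @export
generator_config <- function(seed = 1L, n_groups = 10, foods_per_group = 20,
                             products_per_group = 10, perturbation = 0.10,
                             name_model = list(), unmatchable_fraction = 0.025,
                             zero_energy_fraction = 0.03,
                             missing_field_fraction = 0.03,
                             factors = energy_factors()) {
  nm <- utils::modifyList(
    list(tokens_per_food = 2:4, shuffle_prob = 0.5, drop_prob = 0.15,
         insert_prob = 0.15, brand_prob = 1),
    name_model
  )
  probs <- c(nm$shuffle_prob, nm$drop_prob, nm$insert_prob, nm$brand_prob,
             unmatchable_fraction, zero_energy_fraction, missing_field_fraction)
  if (any(probs < 0 | probs > 1)) {
    abort_config("All generator probabilities must be in [0, 1].")
  }
  if (perturbation < 0) abort_config("`perturbation` must be >= 0.")
  if (any(foods_per_group < 1)) {
    abort_config("Each group needs at least one reference food.")
  }
  structure(
    list(seed = as.integer(seed), n_groups = n_groups,
         foods_per_group = foods_per_group,
         products_per_group = products_per_group,
         perturbation = perturbation, name_model = nm,
         unmatchable_fraction = unmatchable_fraction,
         zero_energy_fraction = zero_energy_fraction,
         missing_field_fraction = missing_field_fraction,
         factors = factors),
    class = "generator_config"
  )
}

SYLLABLES <- c(
  "ba", "be", "bo", "da", "de", "do", "ka", "ke", "ko", "la", "le", "lo",
  "ma", "me", "mo", "na", "ne", "no", "ra", "re", "ro", "sa", "se", "so",
  "ta", "te", "to", "va", "ve", "vo", "zi", "zu"
)

make_words <- function(n) {
  vapply(seq_len(n), function(i) {
    paste(sample(SYLLABLES, sample(2:3, 1), replace = TRUE), collapse = "")
  }, character(1))
}

sample_count <- function(x) if (length(x) == 1L) x else sample(x, 1L)

#' Generate a synthetic linkage benchmark
#'
#' Draws reference foods group by group, clones matched products from
#' them with multiplicative nutrient noise and corrupted names, adds
#' fresh unmatchable products, and flags the designated fractions as
#' zero-energy or missing-field. Returns the dataset together with the
#' ground-truth linkage, so recovery of the truth by the matching
#' pipeline can be measured with [evaluate_recovery()].
#'
#' @param config A [generator_config()].
#' @return List with `dataset` (a [linkage_dataset()]), `truth` (tibble
#'   `product_id`, `true_food_id`; `NA` for unmatchable products), and
#'   the `config` used.
#' @export
generate_linkage <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  withr::with_seed(config$seed, generate_linkage_impl(config))
}

generate_linkage_impl <- function(config) {
  f <- config$factors
  nm <- config$name_model
  groups <- sprintf("G%02d", seq_len(config$n_groups))
  brand_pool <- make_words(max(4L, 2L * config$n_groups))

  foods <- list()
  for (g in groups) {
    vocab <- make_words(12L)
    # group nutrient archetype, grams (mg for sodium) per 100 g
    mu <- c(carb = stats::rlnorm(1, log(30), 0.6),
            protein = stats::rlnorm(1, log(8), 0.6),
            fat = stats::rlnorm(1, log(10), 0.6),
            sodium = stats::rlnorm(1, log(250), 0.7))
    n_food <- sample_count(config$foods_per_group)
    for (i in seq_len(n_food)) {
      carb <- stats::rlnorm(1, log(mu[["carb"]]), 0.25)
      protein <- stats::rlnorm(1, log(mu[["protein"]]), 0.25)
      fat <- stats::rlnorm(1, log(mu[["fat"]]), 0.25)
      sugar <- carb * stats::runif(1, 0.1, 0.8)
      fiber <- carb * stats::runif(1, 0, 0.25)
      satfat <- fat * stats::runif(1, 0.1, 0.7)
      sodium <- stats::rlnorm(1, log(mu[["sodium"]]), 0.4)
      energy <- f[["carb"]] * carb + f[["protein"]] * protein + f[["fat"]] * fat
      n_tok <- sample_count(nm$tokens_per_food)
      name <- paste(sample(vocab, min(n_tok, length(vocab))), collapse = " ")
      foods[[length(foods) + 1L]] <- tibble(
        blocking_group = g, name = name, vocab = list(vocab),
        energy_kcal = energy, carb_g = carb, protein_g = protein, fat_g = fat,
        satfat_g = satfat, sugar_g = sugar, fiber_g = fiber, sodium_mg = sodium
      )
    }
  }
  foods <- dplyr::bind_rows(foods)
  foods$food_id <- sprintf("F%04d", seq_len(nrow(foods)))

  corrupt_name <- function(name, vocab) {
    tok <- strsplit(name, " ", fixed = TRUE)[[1]]
    if (stats::runif(1) < nm$shuffle_prob && length(tok) > 1L) {
      tok <- sample(tok)
    }
    if (stats::runif(1) < nm$drop_prob && length(tok) > 1L) {
      tok <- tok[-sample(length(tok), 1L)]
    }
    if (stats::runif(1) < nm$insert_prob) {
      pos <- sample(length(tok) + 1L, 1L)
      tok <- append(tok, sample(vocab, 1L), after = pos - 1L)
    }
    paste(tok, collapse = " ")
  }

  products <- list()
  truth <- list()
  pid <- 0L
  for (g in groups) {
    gfoods <- foods[foods$blocking_group == g, , drop = FALSE]
    n_prod <- sample_count(config$products_per_group)
    for (i in seq_len(n_prod)) {
      pid <- pid + 1L
      product_id <- sprintf("P%04d", pid)
      unmatchable <- stats::runif(1) < config$unmatchable_fraction
      if (unmatchable) {
        # fresh profile with no true counterpart, drawn like a food
        src <- gfoods[sample(nrow(gfoods), 1L), , drop = FALSE]
        prof <- c(carb = stats::rlnorm(1, log(src$carb_g), 0.8),
                  protein = stats::rlnorm(1, log(src$protein_g), 0.8),
                  fat = stats::rlnorm(1, log(src$fat_g), 0.8))
        carb <- prof[["carb"]]; protein <- prof[["protein"]]; fat <- prof[["fat"]]
        satfat <- fat * stats::runif(1, 0.1, 0.7)
        sugar <- carb * stats::runif(1, 0.1, 0.8)
        fiber <- carb * stats::runif(1, 0, 0.25)
        sodium <- stats::rlnorm(1, log(max(src$sodium_mg, 1)), 0.8)
        subcat <- paste(sample(src$vocab[[1]], 2L), collapse = " ")
        true_id <- NA_character_
      } else {
        src <- gfoods[sample(nrow(gfoods), 1L), , drop = FALSE]
        p <- config$perturbation
        m <- exp(stats::runif(7, -log1p(p), log1p(p)))
        carb <- src$carb_g * m[1]; protein <- src$protein_g * m[2]
        fat <- src$fat_g * m[3]; satfat <- src$satfat_g * m[4]
        sugar <- src$sugar_g * m[5]; fiber <- src$fiber_g * m[6]
        sodium <- src$sodium_mg * m[7]
        subcat <- corrupt_name(src$name, src$vocab[[1]])
        true_id <- src$food_id
      }
      energy <- f[["carb"]] * carb + f[["protein"]] * protein + f[["fat"]] * fat
      brand <- if (stats::runif(1) < nm$brand_prob) sample(brand_pool, 1L) else ""
      products[[length(products) + 1L]] <- tibble(
        product_id = product_id, subcategory = subcat, brand = brand,
        name = if (nzchar(brand)) paste0(subcat, ", ", brand) else subcat,
        blocking_group = g,
        energy_kcal = energy, carb_g = carb, protein_g = protein, fat_g = fat,
        satfat_g = satfat, sugar_g = sugar, fiber_g = fiber, sodium_mg = sodium
      )
      truth[[length(truth) + 1L]] <- tibble(product_id = product_id,
                                            true_food_id = true_id)
    }
  }
  products <- dplyr::bind_rows(products)
  truth <- dplyr::bind_rows(truth)

  n <- nrow(products)
  n_zero <- round(config$zero_energy_fraction * n)
  n_miss <- round(config$missing_field_fraction * n)
  flagged <- sample(n, min(n, n_zero + n_miss))
  zero_idx <- flagged[seq_len(min(n_zero, length(flagged)))]
  miss_idx <- setdiff(flagged, zero_idx)
  products$energy_kcal[zero_idx] <- 0
  nutrient_cols <- setdiff(profile_fields(), "energy_kcal")
  for (i in miss_idx) {
    col <- sample(nutrient_cols, 1L)  # draw once: the index must not differ
    products[[col]][i] <- NA_real_    # between the read and write of `[[<-`
  }

  reference <- foods[c("food_id", "name", "blocking_group", profile_fields())]
  screened <- screen_eligibility(products)
  dataset <- linkage_dataset(screened$products, reference)
  list(dataset = dataset, truth = truth, config = config)
}

#' Recovery of the ground truth by a match report
#'
#' Measures how well the pipeline's final suggestion sets recover a
#' known linkage: *suggestion recall* is the fraction of eligible,
#' truly-matched products whose true food appears in the final
#' suggestion set, and *top-rank recall* the fraction whose true food is
#' ranked first. Products with no true counterpart or routed directly to
#' manual matching are excluded from the denominators.
#'
#' @param report A `match_report` from [run_schedule()].
#' @param truth Tibble `product_id`, `true_food_id` (as returned by
#'   [generate_linkage()]).
#' @return List with `suggestion_recall`, `top_rank_recall`,
#'   `n_evaluated`, and `by_level` (a tibble broken down by final match
#'   level). Recalls are `NA` (flagged via `n_evaluated = 0`) when no
#'   product is evaluable.
#' @export
evaluate_recovery <- function(report, truth) {
  stopifnot(inherits(report, "match_report"))
  ids <- report$products$product_id
  if (!all(truth$product_id %in% ids) || !all(ids %in% truth$product_id)) {
    abort_validation("`report` and `truth` must cover the same products.")
  }
  prods <- dplyr::left_join(report$products, truth, by = "product_id")
  prods <- prods[prods$route == "algorithm" & !is.na(prods$true_food_id), , drop = FALSE]
  if (nrow(prods) == 0L) {
    return(list(suggestion_recall = NA_real_, top_rank_recall = NA_real_,
                n_evaluated = 0L, by_level = tibble()))
  }
  cand <- report$candidates
  hit <- vapply(seq_len(nrow(prods)), function(i) {
    set <- cand[cand$product_id == prods$product_id[i], , drop = FALSE]
    prods$true_food_id[i] %in% set$food_id
  }, logical(1))
  top <- vapply(seq_len(nrow(prods)), function(i) {
    set <- cand[cand$product_id == prods$product_id[i], , drop = FALSE]
    nrow(set) > 0L && set$food_id[set$rank == 1L] == prods$true_food_id[i]
  }, logical(1))
  by_level <- dplyr::summarise(
    dplyr::group_by(tibble(level = prods$level, hit = hit, top = top), .data$level),
    n = dplyr::n(),
    suggestion_recall = mean(.data$hit),
    top_rank_recall = mean(.data$top),
    .groups = "drop"
  )
  list(suggestion_recall = mean(hit), top_rank_recall = mean(top),
       n_evaluated = nrow(prods), by_level = by_level)
}

#' Write a synthetic benchmark to disk
#'
#' Writes `products.csv`, `reference.csv`, `truth.csv` and
#' `generator_config.yaml` under `dir`.
#'
#' @param sim Result of [generate_linkage()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_dataset(sim$dataset, dir)
  readr::write_csv(sim$truth, file.path(dir, "truth.csv"), na = "")
  cfg <- sim$config
  cfg$factors <- as.list(unclass(cfg$factors))
  yaml::write_yaml(unclass(cfg), file.path(dir, "generator_config.yaml"))
  invisible(dir)
}
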