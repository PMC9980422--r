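# Fixture builders shared across tests. All fixtures are built in code.

# A complete product row; energy defaults to the macro-derived value so
# percent-of-calories shares are well behaved.
make_product <- function(product_id = "P1", subcategory = "toy snack",
                         brand = "acme", blocking_group = "G1",
                         energy = NULL, carb = 50, protein = 10, fat = 15,
                         satfat = 5, sugar = 20, fiber = 5, sodium = 300,
                         name = NULL) {
  energy <- energy %||% (4 * carb + 4 * protein + 9 * fat)
  tibble::tibble(
    product_id = product_id, subcategory = subcategory, brand = brand,
    name = name %||% paste(subcategory, brand, sep = ", "),
    blocking_group = blocking_group,
    energy_kcal = energy, carb_g = carb, protein_g = protein, fat_g = fat,
    satfat_g = satfat, sugar_g = sugar, fiber_g = fiber, sodium_mg = sodium,
    eligible = TRUE, exclusion_reason = NA_character_
  )
}

make_food <- function(food_id = "F1", name = "toy snack generic",
                      blocking_group = "G1", energy = NULL,
                      carb = 50, protein = 10, fat = 15, satfat = 5,
                      sugar = 20, fiber = 5, sodium = 300) {
  energy <- energy %||% (4 * carb + 4 * protein + 9 * fat)
  tibble::tibble(
    food_id = food_id, name = name, blocking_group = blocking_group,
    energy_kcal = energy, carb_g = carb, protein_g = protein, fat_g = fat,
    satfat_g = satfat, sugar_g = sugar, fiber_g = fiber, sodium_mg = sodium
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_temp_csv <- function(df, name = "fixture.csv") {
  path <- file.path(withr::local_tempdir(.local_envir = parent.frame()), name)
  readr::write_csv(df, path, na = "")
  path
}

# A two-rater decision log from verdict pairs.
make_decision_log <- function(pairs, stage = "algorithm") {
  n <- length(pairs)
  tibble::tibble(
    product_id = rep(sprintf("P%03d", seq_len(n)), each = 2),
    rater_id = rep(c("r1", "r2"), n),
    stage = stage,
    verdict = unlist(pairs),
    resolution_round = 1L
  )
}
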