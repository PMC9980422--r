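test_that("shipped presets carry the standard threshold table", {
  p <- sift_presets()
  expect_equal(p$first$macro_threshold, 20)
  expect_equal(p$first$secondary_threshold, 10)
  expect_equal(p$first$sodium_threshold, 0.5)
  expect_false(p$first$use_min_fuzzy)
  expect_true(p$first$use_fuzzy_optimization)
  expect_equal(p$first_plus$macro_threshold, 60)
  expect_equal(p$first_plus$secondary_threshold, 60)
  expect_equal(p$first_plus$min_fuzzy_score, 50)
  expect_true(p$first_plus$use_min_fuzzy)
  expect_false(p$first_plus$use_fuzzy_optimization)
  expect_equal(p$second$macro_threshold, 40)
  expect_true(is.infinite(p$third$macro_threshold))
  expect_true(is.infinite(p$third$sodium_threshold))
})

test_that("the candidate pool is the shared blocking group", {
  ref <- dplyr::bind_rows(
    make_food("F1", blocking_group = "G1"),
    make_food("F2", blocking_group = "G1"),
    make_food("F3", blocking_group = "G1"),
    make_food("F4", blocking_group = "G2"),
    make_food("F5", blocking_group = "G2")
  )
  p <- make_product(blocking_group = "G1")
  expect_equal(candidate_pool(p, ref)$food_id, c("F1", "F2", "F3"))
  expect_warning(
    pool <- candidate_pool(make_product(blocking_group = "G9"), ref),
    "no reference foods"
  )
  expect_equal(nrow(pool), 0L)
  expect_equal(nrow(candidate_pool(p, ref, blocking = FALSE)), 5L)
})

test_that("nutrient filters apply all-conditions-simultaneously, strictly below", {
  p <- make_product(energy = 400, carb = 50, protein = 10, fat = 15)
  pool <- dplyr::bind_rows(
    make_food("FX", energy = 400, carb = 50, protein = 10, fat = 15),  # identical
    make_food("FY", energy = 400, carb = 75, protein = 10, fat = 15)   # carb +25 pp
  )
  expect_equal(filter_macros(p, pool, 20)$food_id, "FX")
  expect_equal(filter_macros(p, pool, Inf)$food_id, c("FX", "FY"))
  # boundary: a difference exactly at the threshold is removed
  pb <- make_product(energy = 400, sugar = 20)
  fb <- make_food("FB", energy = 400, sugar = 30)  # sugar diff = 10 pp exactly
  expect_equal(nrow(filter_secondary(pb, fb, 10)), 0L)
  expect_equal(nrow(filter_secondary(pb, fb, 10, strict = FALSE)), 1L)
  expect_equal(nrow(filter_secondary(pb, fb, Inf)), 1L)
  # missing food-side nutrient fails a binding filter, passes a disabled one
  fm <- make_food("FM", fiber = NA_real_)
  expect_equal(nrow(filter_secondary(make_product(), fm, 10)), 0L)
  expect_equal(nrow(filter_secondary(make_product(), fm, Inf)), 1L)
})

test_that("the sodium filter applies only to non-zero-sodium products", {
  pool <- dplyr::bind_rows(
    make_food("F140", sodium = 140),
    make_food("F300", sodium = 300)
  )
  p <- make_product(sodium = 100)
  expect_equal(filter_sodium(p, pool, 0.5)$food_id, "F140")  # 0.4 < 0.5 < 2.0
  p0 <- make_product(sodium = 0)
  expect_equal(filter_sodium(p0, pool, 0.5)$food_id, c("F140", "F300"))
})

test_that("fuzzy filters threshold and arg-max the name score", {
  p <- make_product(name = "oat flakes, acme")
  pool <- dplyr::bind_rows(
    make_food("FA", name = "flakes oat"),          # score 100
    make_food("FB", name = "oat bran porridge"),   # partial overlap
    make_food("FC", name = "zzz qqq")              # no overlap
  )
  expect_equal(filter_min_fuzzy(p, pool, 0)$food_id, c("FA", "FB", "FC"))
  expect_equal(filter_min_fuzzy(p, pool, 100)$food_id, "FA")
  sc <- partial_token_sort_ratio(p$name, pool$name)
  # min-score boundary: inclusive by default, exclusive on request
  expect_true("FB" %in% filter_min_fuzzy(p, pool, sc[2])$food_id)
  expect_false("FB" %in% filter_min_fuzzy(p, pool, sc[2], inclusive = FALSE)$food_id)
  expect_equal(filter_fuzzy_optimization(p, pool)$food_id, "FA")
  # ties all kept
  tie <- dplyr::bind_rows(make_food("T1", name = "oat flakes"),
                          make_food("T2", name = "flakes oat"),
                          make_food("T3", name = "zzz"))
  expect_equal(filter_fuzzy_optimization(p, tie)$food_id, c("T1", "T2"))
  expect_equal(nrow(filter_fuzzy_optimization(p, pool[0, ])), 0L)
})

test_that("run_sift composes the cascade on the printed toy fixture", {
  p <- make_product(energy = 400, carb = 50, protein = 10, fat = 15,
                    satfat = 5, sugar = 20, fiber = 5, sodium = 300)
  ref <- dplyr::bind_rows(
    make_food("X", energy = 400, carb = 50, protein = 10, fat = 15,
              satfat = 5, sugar = 20, fiber = 5, sodium = 300,
              name = p$name),
    make_food("Y", energy = 400, carb = 75, protein = 10, fat = 15,
              satfat = 5, sugar = 20, fiber = 5, sodium = 300)
  )
  got <- run_sift(p, ref, sift_presets()$first)
  expect_equal(got$food_id, "X")
  expect_equal(got$max_diff, 0)
  expect_equal(got$fuzzy_score, 100L)
  expect_equal(got$sift_name, "first")

  # all-infinity parameters with optimization off: the whole group pool
  loose <- sift_params("loose", Inf, Inf, Inf, use_fuzzy_optimization = FALSE)
  expect_setequal(run_sift(p, ref, loose)$food_id, c("X", "Y"))

  # third preset: only fuzzy optimization binds
  got3 <- run_sift(p, ref, sift_presets()$third)
  expect_equal(got3$food_id, "X")

  # ineligible product -> usage error
  pi <- make_product(energy = 0)
  pi$eligible <- FALSE
  expect_error(run_sift(pi, ref, loose), class = "nutrilink_usage_error")
})

test_that("every filter returns a subset and a perfect twin always survives", {
  withr::with_seed(21, {
    for (i in 1:40) {
      inst <- random_instance()
      params <- random_params()
      pool <- suppressWarnings(candidate_pool(inst$product, inst$reference))
      out <- suppressWarnings(run_sift(inst$product, inst$reference, params))
      expect_true(all(out$food_id %in% pool$food_id))

      # plant a same-group twin with the product's name and profile
      twin <- make_food("TWIN", name = inst$product$name,
                        blocking_group = inst$product$blocking_group)
      for (col in profile_fields()) twin[[col]] <- inst$product[[col]]
      ref2 <- dplyr::bind_rows(inst$reference, twin)
      params2 <- random_params()
      out2 <- suppressWarnings(run_sift(inst$product, ref2, params2))
      expect_true("TWIN" %in% out2$food_id)
    }
  })
})

test_that("with fuzzy optimization off, looser thresholds never shrink the pool", {
  withr::with_seed(31, {
    for (i in 1:60) {
      inst <- random_instance()
      mac <- sort(sample(c(5, 10, 20, 40, 60, Inf), 2))
      sec <- sort(sample(c(5, 10, 20, 40, 60, Inf), 2))
      sod <- sort(sample(c(0.1, 0.25, 0.5, 1, Inf), 2))
      fz <- sort(sample(c(0, 30, 50, 80), 2), decreasing = TRUE)
      tight <- sift_params("tight", mac[1], sec[1], sod[1], fz[1],
                           use_min_fuzzy = TRUE, use_fuzzy_optimization = FALSE)
      loose <- sift_params("loose", mac[2], sec[2], sod[2], fz[2],
                           use_min_fuzzy = TRUE, use_fuzzy_optimization = FALSE)
      a <- suppressWarnings(run_sift(inst$product, inst$reference, tight))
      b <- suppressWarnings(run_sift(inst$product, inst$reference, loose))
      expect_true(all(a$food_id %in% b$food_id))
    }
  })
})
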