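test_that("agreement rates reproduce the worked verdict-pair examples", {
  log <- make_decision_log(list(c("A", "A"), c("A", "B"),
                                c(REFUSE, REFUSE), c("A", REFUSE)))
  expect_equal(agreement_selection(log), 50)
  expect_equal(agreement_manual_needed(log), 75)

  all_same <- make_decision_log(list(c("A", "A"), c(REFUSE, REFUSE)))
  expect_equal(agreement_selection(all_same), 100)
  expect_equal(agreement_manual_needed(all_same), 100)

  split_log <- make_decision_log(list(c("A", REFUSE)))
  expect_equal(agreement_manual_needed(split_log), 0)

  manual <- make_decision_log(list(c("X", "X"), c("X", "Y"),
                                   c(UNMATCHABLE, UNMATCHABLE)),
                              stage = "manual")
  expect_equal(round(agreement_manual_selection(manual), 1), 66.7)
  expect_equal(agreement_manual_selection(
    make_decision_log(list(c("X", "Y"), c("X", UNMATCHABLE)), stage = "manual")
  ), 0)
})

test_that("agreement rates validate their inputs", {
  log <- make_decision_log(list(c("A", "A")))
  expect_error(agreement_selection(log[0, ]), class = "nutrilink_validation_error")
  # a missing decision for one rater
  expect_error(agreement_selection(log[-1, ]), class = "nutrilink_validation_error")
  # duplicated decision
  expect_error(agreement_selection(log[c(1, 1, 2), ]),
               class = "nutrilink_validation_error")
  # three raters without disambiguation
  three <- dplyr::bind_rows(log, tibble::tibble(
    product_id = "P001", rater_id = "r3", stage = "algorithm",
    verdict = "A", resolution_round = 1L
  ))
  expect_error(agreement_selection(three), class = "nutrilink_validation_error")
  expect_equal(agreement_selection(three, raters = c("r1", "r2")), 100)
  # later resolution rounds are excluded from the rates
  withres <- dplyr::bind_rows(log, tibble::tibble(
    product_id = "P001", rater_id = "r3", stage = "algorithm",
    verdict = "B", resolution_round = 2L
  ))
  expect_equal(agreement_selection(withres), 100)
})

test_that("identical verdicts imply dichotomy agreement on random logs", {
  withr::with_seed(41, {
    for (i in 1:500) {
      n <- sample(1:12, 1)
      verdicts <- c("A", "B", "C", REFUSE)
      pairs <- replicate(n, sample(verdicts, 2, replace = TRUE), simplify = FALSE)
      log <- make_decision_log(pairs)
      expect_gte(agreement_manual_needed(log), agreement_selection(log))
    }
  })
})

test_that("algorithm accuracy counts adjudicated picks among suggestions", {
  sim <- generate_linkage(generator_config(seed = 31, n_groups = 3,
                                           foods_per_group = 6,
                                           products_per_group = 5,
                                           unmatchable_fraction = 0,
                                           zero_energy_fraction = 0,
                                           missing_field_fraction = 0))
  report <- run_schedule(sim$dataset)
  prods <- report$products
  suggested <- prods$product_id[!is.na(prods$level) & prods$level != "0"]
  # adjudicate: first suggestion for an arbitrary 70%, REFUSE for the rest
  take <- seq_along(suggested) %% 10 < 7
  verdicts <- vapply(seq_along(suggested), function(i) {
    if (!take[i]) return(REFUSE)
    set <- report$candidates[report$candidates$product_id == suggested[i], ]
    set$food_id[set$rank == 1]
  }, character(1))
  adj <- tibble::tibble(product_id = suggested, verdict = verdicts)
  acc <- algorithm_accuracy(report, adj)
  overall <- acc[acc$category == "Overall" & acc$level == "all", ]
  expect_equal(overall$n_products, length(suggested))
  expect_equal(overall$n_accurate, sum(take))
  expect_equal(overall$pct_accurate,
               nutrilink:::round_half_up(100 * mean(take), 1))
  # category rows aggregate exactly to the overall row
  cat_all <- acc[acc$category != "Overall" & acc$level == "all", ]
  expect_equal(sum(cat_all$n_products), overall$n_products)
  expect_equal(sum(cat_all$n_accurate), overall$n_accurate)
  # level rows partition the all row
  lv <- acc[acc$category == "Overall" & acc$level != "all", ]
  expect_equal(sum(lv$n_products), overall$n_products)
  # refusing everything gives 0%
  all_ref <- tibble::tibble(product_id = suggested, verdict = REFUSE)
  acc0 <- algorithm_accuracy(report, all_ref)
  expect_equal(acc0$pct_accurate[acc0$category == "Overall" & acc0$level == "all"], 0)
  # an adjudicated food outside the suggestion set is an integrity error
  bad <- adj
  bad$verdict[which(take)[1]] <- "NOT_A_SUGGESTION"
  expect_error(algorithm_accuracy(report, bad),
               class = "nutrilink_integrity_error")
  # a missing adjudication is a validation error
  expect_error(algorithm_accuracy(report, adj[-1, ]),
               class = "nutrilink_validation_error")
})

test_that("process accuracy tabulates terminal outcomes per category", {
  prods <- dplyr::bind_rows(
    make_product("P1", subcategory = "s1"),
    make_product("P2", subcategory = "s1"),
    make_product("P3", subcategory = "s2"),
    make_product("P4", subcategory = "s2")
  )
  outcomes <- tibble::tibble(
    product_id = c("P1", "P2", "P3", "P4"),
    outcome = c("matched", "matched", "matched", "unmatchable")
  )
  rollup <- tibble::tibble(subcategory = c("s1", "s2"), category = c("C", "C"))
  tab <- process_accuracy(prods, outcomes, rollup)
  expect_equal(tab$n_products, c(4L, 4L))  # category C + Total
  expect_equal(tab$pct_matched, c(75, 75))
  tab2 <- process_accuracy(prods, outcomes)
  expect_equal(tab2$pct_matched[tab2$category == "Total"], 75)
  expect_equal(tab2$n_matched[tab2$category == "s1"], 2L)
  expect_error(process_accuracy(prods, outcomes[-1, ]),
               class = "nutrilink_validation_error")
  expect_error(
    process_accuracy(prods, dplyr::mutate(outcomes, outcome = "eaten")),
    class = "nutrilink_validation_error"
  )
  # rollup must be total
  expect_error(
    process_accuracy(prods, outcomes,
                     tibble::tibble(subcategory = "s1", category = "C")),
    class = "nutrilink_validation_error"
  )
})

test_that("threshold sweeps summarize sqrt counts and are monotone", {
  sim <- generate_linkage(generator_config(seed = 13, n_groups = 3,
                                           foods_per_group = 8,
                                           products_per_group = 4))
  grid <- c(5, 10, 20, 40, Inf)
  sw <- threshold_sweep(sim$dataset, grid, vary = "macro",
                        secondary_threshold = 40, sodium_threshold = 0.5)
  expect_equal(nrow(sw), length(grid))
  # percentiles are ordered within each row and non-decreasing along the grid
  expect_true(all(sw$p0 <= sw$p25 & sw$p25 <= sw$p50 &
                  sw$p50 <= sw$p75 & sw$p75 <= sw$p100))
  for (col in c("p0", "p25", "p50", "p75", "p100")) {
    expect_true(all(diff(sw[[col]]) >= -1e-12))
  }
  # all-infinity thresholds recover the blocking-pool sizes
  open <- threshold_sweep(sim$dataset, Inf, vary = "macro",
                          secondary_threshold = Inf, sodium_threshold = Inf)
  eligible <- sim$dataset$products[sim$dataset$products$eligible, ]
  pool_sizes <- vapply(eligible$blocking_group, function(g) {
    sum(sim$dataset$reference$blocking_group == g)
  }, integer(1))
  expect_equal(open$p100, max(sqrt(pool_sizes)))
  expect_equal(open$p0, min(sqrt(pool_sizes)))
  # sodium sweep runs with its own fixed defaults
  sw2 <- threshold_sweep(sim$dataset, c(0.25, 0.5, 1), vary = "sodium",
                         macro_threshold = 20, secondary_threshold = 10)
  expect_true(all(diff(sw2$p50) >= -1e-12))
  # empty dataset -> empty summary
  empty <- linkage_dataset(make_product()[0, ], make_food())
  expect_equal(nrow(threshold_sweep(empty, grid)), 0L)
})
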