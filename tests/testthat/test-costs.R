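test_that("present value matches closed forms and is monotone in the rate", {
  expect_equal(present_value(data.frame(year = c(0, 1, 2), amount = 1), 0), 3)
  expect_equal(present_value(data.frame(year = 1, amount = 100), 0.03),
               100 / 1.03, tolerance = 1e-12)
  expect_equal(present_value(list(), 0.03), 0)
  expect_equal(present_value(list(c(0, 5), c(2, 10)), 0.05),
               5 + 10 / 1.05^2, tolerance = 1e-12)
  expect_error(present_value(data.frame(year = 0, amount = 1), -0.01),
               "non-negative")
  ## non-increasing in rate for non-negative streams
  set.seed(101)
  stream <- data.frame(year = 0:10, amount = runif(11))
  pv <- vapply(seq(0, 0.2, by = 0.02), present_value, numeric(1),
               stream = stream)
  expect_true(all(diff(pv) <= 1e-12))
})

test_that("intervention cost equation is homogeneous and matches anchors", {
  p <- calibrated_params()
  wm <- p$interventions$WM
  expect_equal(intervention_total_cost(wm, 0.6 * 91000), 42e6,
               tolerance = 1e-6)
  expect_equal(intervention_total_cost(p$interventions$PPE, 91000), 81.1e6,
               tolerance = 1e-6)
  expect_equal(intervention_total_cost(wm, 0), 0)
  ## doubling workers doubles cost; doubling the factor halves it
  c1 <- intervention_total_cost(wm, 1000)
  expect_equal(intervention_total_cost(wm, 2000), 2 * c1, tolerance = 1e-12)
  expect_equal(intervention_total_cost(wm, 1000, protection_factor = 10),
               c1 / 2, tolerance = 1e-12)
  ## PPE is invariant under the protection factor argument (fixed at 1)
  ppe <- p$interventions$PPE
  expect_equal(intervention_total_cost(ppe, 1000, protection_factor = 5),
               intervention_total_cost(ppe, 1000))
  expect_error(intervention_total_cost(wm, 100, protection_factor = 0),
               "positive")
  expect_error(intervention_total_cost(default_parameters()$interventions$WM,
                                       100), "calibrate")
})

test_that("strategy costs decompose by member as published", {
  p <- calibrated_params()
  costs <- strategy_cost("WM-LEV-PPE", p)
  expect_equal(unname(costs[c("WM", "LEV", "PPE")]),
               c(42e6, 15.5e6, 81.1e6), tolerance = 1e-6)
  expect_equal(unname(strategy_cost("LEV", p)), 15.5e6, tolerance = 1e-6)
  expect_length(strategy_cost(NULL, p), 0)
  ## PPE overlays the whole workforce in mixed strategies
  expect_equal(unname(strategy_cost("LEV-PPE", p)[["PPE"]]), 81.1e6,
               tolerance = 1e-6)
})

test_that("lifetime case cost behaves in limiting cases and is additive", {
  p <- calibrated_params()
  model <- build_lifetime_cost_model(p)
  profiles <- expand.grid(age_bin = c(1, 5, 10, 13),
                          sex = c("male", "female"),
                          survives = c(TRUE, FALSE), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(profiles))) {
    cb <- lifetime_case_cost(as.list(profiles[i, ]), model, p$econ)
    expect_equal(cb$total, cb$direct + cb$indirect + cb$intangible,
                 tolerance = 1e-9)
    expect_true(all(unlist(cb) >= 0))
  }
  expect_error(lifetime_case_cost(list(age_bin = 14, sex = "male",
                                       survives = FALSE), model, p$econ),
               "age bin")

  ## doubling the QALY value doubles intangible, leaves direct unchanged
  q <- p
  q$econ$qaly_value <- 2 * p$econ$qaly_value
  prof <- list(age_bin = 10, sex = "male", survives = FALSE)
  cb1 <- lifetime_case_cost(prof, model, p$econ)
  cb2 <- lifetime_case_cost(prof, build_lifetime_cost_model(q), q$econ)
  expect_equal(cb2$intangible, 2 * cb1$intangible, tolerance = 1e-9)
  expect_equal(cb2$direct, cb1$direct, tolerance = 1e-9)

  ## zero discounting and a one-year horizon give the undiscounted annual value
  z <- default_parameters()
  z$econ$discount_rate <- 0
  model0 <- build_lifetime_cost_model(z)
  model0$life_expectancy_by_age_sex[13, "male"] <- 1
  cb <- lifetime_case_cost(list(age_bin = 13, sex = "male", survives = FALSE),
                           model0, z$econ)
  expect_equal(cb$indirect, z$econ$home_production_value, tolerance = 1e-9)
  expect_equal(cb$intangible,
               z$econ$qaly_value * z$econ$quality_weight, tolerance = 1e-9)
})

test_that("expected case cost matches the calibrated per-case cost and shares", {
  p <- calibrated_params()
  cc <- expected_case_cost(p)
  expect_equal(cc$total, 189e6 / 110, tolerance = 1e-6)
  shares <- c(cc$direct, cc$indirect, cc$intangible) / cc$total
  target <- c(9.5, 41.2, 133.9) / (9.5 + 41.2 + 133.9)
  expect_equal(shares, target, tolerance = 0.005)
  ## lowering the QALY value lowers the intangible share, leaves direct cost fixed
  q <- p
  q$econ$qaly_value <- 100000
  cc2 <- expected_case_cost(q)
  expect_lt(cc2$intangible / cc2$total, cc$intangible / cc$total)
  expect_equal(cc2$direct, cc$direct, tolerance = 1e-6)
  expect_equal(cc2$intangible, cc$intangible * 100000 / 150000,
               tolerance = 1e-9)
})

test_that("mortality-driven losses shrink when everyone survives and returns", {
  p <- calibrated_params()
  q <- p
  q$econ$survival_probability <- 1
  q$econ$participation_after_treatment <- 1
  cc_all_survive <- expected_case_cost(q)
  cc <- expected_case_cost(p)
  expect_lt(cc_all_survive$indirect, cc$indirect)
  expect_lt(cc_all_survive$intangible, cc$intangible)
})
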