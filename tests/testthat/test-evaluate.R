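test_that("strategy evaluation satisfies the accounting identities", {
  p <- calibrated_params()
  ev <- evaluate_all(p)
  expect_equal(nrow(ev), 7)
  expect_equal(ev$strategy, strategy_names())
  ## net benefit identity and B/C sign equivalence, machine-checked
  expect_equal(ev$net_benefit, ev$averted_total - ev$cost_total,
               tolerance = 1e-9)
  expect_equal(ev$averted_total,
               ev$averted_direct + ev$averted_indirect + ev$averted_intangible,
               tolerance = 1e-9)
  expect_true(all((ev$bc_ratio > 1) == (ev$net_benefit > 0)))
  expect_true(all(ev$net_benefit > 0))
})

test_that("published rankings hold under the default parameterization", {
  ev <- evaluate_all(calibrated_params())
  expect_equal(ev$strategy[which.max(ev$cases_averted)], "WM-LEV-PPE")
  expect_equal(ev$strategy[which.max(ev$net_benefit)], "WM-LEV")
  expect_equal(ev$strategy[which.max(ev$bc_ratio)], "LEV")
  ## WM-only strategy: 55 averted at $42.0M cost gives a $52.5M net benefit
  wm <- ev[ev$strategy == "WM", ]
  expect_equal(wm$net_benefit, 52.5e6, tolerance = 1e-6)
  expect_equal(round(wm$bc_ratio, 1), 2.2)
})

test_that("an intervention with no effect yields zero benefit and no B/C ratio", {
  p <- calibrated_params()
  for (nm in c("WM", "LEV", "PPE"))
    p$interventions[[nm]]$calibrated_risk_reduction <- 0
  r <- evaluate_strategy(p, "WM-LEV")
  expect_equal(r$cases_averted, 0)
  expect_equal(r$averted$total, 0)
  expect_lt(r$net_benefit, 0)        # still pays the implementation cost
  base <- evaluate_strategy(p, NULL)
  expect_equal(base$cases_averted, 0)
  expect_equal(base$net_benefit, 0)
  expect_true(is.na(base$bc_ratio))  # undefined marker, not infinity
})

test_that("one-way sensitivity at the default QALY level is a no-op", {
  p <- calibrated_params()
  res <- one_way_sensitivity(p, "qaly_value", 150000)[[1]]
  ev <- evaluate_all(p)
  for (s in c("WM-LEV-PPE", "WM-LEV", "PPE"))
    expect_equal(res$results$net_benefit[res$results$strategy == s],
                 ev$net_benefit[ev$strategy == s], tolerance = 1e-9)
  expect_equal(unname(res$net_benefit_change), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(res$baseline_cases, 110, tolerance = 1e-9)
  expect_equal(res$baseline_burden, 189e6, tolerance = 1e-3)
})

test_that("net benefit is monotone non-decreasing in the workforce size", {
  p <- calibrated_params()
  grid <- seq(46000, 118000, by = 18000)
  res <- one_way_sensitivity(p, "workers_total", grid)
  for (s in c("WM-LEV-PPE", "WM-LEV", "PPE")) {
    nb <- vapply(res, function(r)
      r$results$net_benefit[r$results$strategy == s], numeric(1))
    expect_true(all(diff(nb) >= -1e-6), info = s)
  }
})

test_that("forced-exposure scenarios keep the calibrated risk scale", {
  p <- calibrated_params()
  res <- one_way_sensitivity(p, "exposure_level", c("low", "high"))
  rs <- p$calibration$risk_scale
  expect_equal(res[[1]]$baseline_cases, 91000 * rs * 9.1e-4, tolerance = 1e-9)
  expect_equal(res[[2]]$baseline_cases, 91000 * rs * 1.4e-3, tolerance = 1e-9)
  ## higher exposure means more cases and a larger burden
  expect_gt(res[[2]]$baseline_burden, res[[1]]$baseline_burden)
})

test_that("QALY sensitivity scales only the intangible benefit, linearly", {
  p <- calibrated_params()
  res <- one_way_sensitivity(p, "qaly_value", c(100000, 200000))
  ev <- evaluate_all(p)
  for (i in c(1, 2)) {
    ratio <- c(100000, 200000)[i] / 150000
    r <- res[[i]]$results
    for (s in c("WM-LEV-PPE", "WM-LEV", "PPE")) {
      here <- r[r$strategy == s, ]
      there <- ev[ev$strategy == s, ]
      expect_equal(here$averted_intangible, ratio * there$averted_intangible,
                   tolerance = 1e-9)
      expect_equal(here$averted_direct, there$averted_direct,
                   tolerance = 1e-9)
      expect_equal(here$cost_total, there$cost_total, tolerance = 1e-9)
    }
  }
})

test_that("unknown sensitivity variables and levels are rejected", {
  p <- calibrated_params()
  expect_error(one_way_sensitivity(p, "discount_rate", 0.05),
               "unknown sensitivity variable")
  expect_error(one_way_sensitivity(p, "exposure_level", "extreme"),
               "unknown exposure level")
})
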