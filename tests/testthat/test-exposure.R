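test_that("coverage allocations match the published protected-worker rows", {
  p <- calibrated_params()
  expected <- list(
    "WM-LEV-PPE" = c("WM+PPE" = 0.6, "LEV+PPE" = 0.4),
    "WM-LEV"     = c("WM" = 0.6, "LEV" = 0.4),
    "WM-PPE"     = c("WM+PPE" = 0.6, "PPE" = 0.4),
    "WM"         = c("WM" = 0.6, "none" = 0.4),
    "LEV-PPE"    = c("LEV+PPE" = 0.4, "PPE" = 0.6),
    "LEV"        = c("LEV" = 0.4, "none" = 0.6),
    "PPE"        = c("PPE" = 1.0)
  )
  protected <- c(1, 1, 1, 0.6, 1, 0.4, 1)
  for (i in seq_along(expected)) {
    s <- names(expected)[i]
    alloc <- allocate_protection(s, p)
    expect_equal(alloc$segments[names(expected[[i]])], expected[[i]],
                 info = s)
    expect_equal(sum(alloc$segments), 1, tolerance = 1e-9, info = s)
    expect_equal(alloc$protected_fraction, protected[i], info = s)
  }
  base <- allocate_protection(NULL, p)
  expect_equal(unname(base$segments["none"]), 1)
  expect_equal(base$protected_fraction, 0)
})

test_that("category shifting follows the concentration thresholds", {
  p <- default_parameters()
  ## WM field effectiveness 0.82 x 0.75 = 0.615: high (0.025) -> 0.0096 -> low
  expect_equal(shift_exposure("high", 0.82 * 0.75, p)$category, "low")
  ## LEV 0.93 x 0.75 = 0.6975: medium (0.025 bound) -> 0.0076 -> low
  expect_equal(shift_exposure("medium", 0.93 * 0.75, p)$category, "low")
  ## zero effectiveness leaves every category unchanged
  for (cat in c("low", "medium", "high"))
    expect_equal(shift_exposure(cat, 0, p)$category, cat)
  ## a weak intervention only moves high to medium
  expect_equal(shift_exposure("high", 0.2, p)$category, "medium")
  expect_error(shift_exposure("high", 1.2, p), "\\[0, 1\\]")
  ## residual risk never exceeds the primary risk
  for (cat in c("low", "medium", "high")) {
    primary <- p$exposure$lifetime_risk[match(cat, p$exposure$name)]
    for (e in seq(0, 1, by = 0.1))
      expect_lte(shift_exposure(cat, e, p)$residual_risk, primary + 1e-15)
  }
})

test_that("expected cases reproduce anchored counts and predict combinations", {
  p <- calibrated_params()
  expect_equal(expected_cases(p), 110, tolerance = 1e-9)
  ## disjoint-coverage additivity: WM-LEV is the sum of its slices
  expect_equal(cases_averted(p, "WM-LEV"), 95, tolerance = 1e-9)
  expect_equal(cases_averted(p, "PPE"), 96, tolerance = 1e-9)
  ## multiplicative residual-risk prediction for the full combination
  r <- p$calibration$risk_reduction
  resid <- 0.6 * 110 * (1 - r[["WM"]]) * (1 - r[["PPE"]]) +
    0.4 * 110 * (1 - r[["LEV"]]) * (1 - r[["PPE"]])
  expect_equal(cases_averted(p, "WM-LEV-PPE"), 110 - resid, tolerance = 1e-9)
  expect_lt(abs(cases_averted(p, "WM-LEV-PPE") - 107) / 107, 0.02)
})

test_that("perfect and null interventions give the limiting case counts", {
  p <- calibrated_params()
  perfect <- p
  for (nm in c("WM", "LEV", "PPE"))
    perfect$interventions[[nm]]$calibrated_risk_reduction <- 1
  expect_equal(expected_cases(perfect, "WM-LEV-PPE"), 0, tolerance = 1e-9)
  expect_equal(expected_cases(perfect, "PPE"), 0, tolerance = 1e-9)

  null <- p
  for (nm in c("WM", "LEV", "PPE"))
    null$interventions[[nm]]$calibrated_risk_reduction <- 0
  for (s in strategy_names())
    expect_equal(cases_averted(null, s), 0, tolerance = 1e-9)
})

test_that("cases averted are bounded, monotone and improved by adding PPE", {
  p <- calibrated_params()
  baseline <- expected_cases(p)
  for (s in strategy_names()) {
    ca <- cases_averted(p, s)
    expect_gte(ca, 0)
    expect_lte(ca, baseline + 1e-9)
  }
  ## monotone in each risk reduction
  for (nm in c("WM", "LEV", "PPE")) {
    prev <- -Inf
    for (rr in seq(0, 1, by = 0.25)) {
      q <- p
      q$interventions[[nm]]$calibrated_risk_reduction <- rr
      ca <- cases_averted(q, "WM-LEV-PPE")
      expect_gte(ca, prev - 1e-9)
      prev <- ca
    }
  }
  ## monotone in WM coverage (WM-only strategy)
  prev <- -Inf
  for (cov in seq(0, 0.6, by = 0.15)) {
    q <- p
    q$interventions$WM$coverage <- cov
    ca <- cases_averted(q, "WM")
    expect_gte(ca, prev - 1e-9)
    prev <- ca
  }
  ## overlaying PPE never decreases cases averted
  expect_gte(cases_averted(p, "WM-PPE"), cases_averted(p, "WM"))
  expect_gte(cases_averted(p, "LEV-PPE"), cases_averted(p, "LEV"))
  expect_gte(cases_averted(p, "WM-LEV-PPE"), cases_averted(p, "WM-LEV"))
})

test_that("category-shift mode gives non-increasing residual risk in effectiveness", {
  p <- calibrated_params()
  p$risk_mode <- "category_shift"
  for (cat in c("low", "medium", "high")) {
    prev <- Inf
    for (e in seq(0, 1, by = 0.05)) {
      rr <- shift_exposure(cat, e, p)$residual_risk
      expect_lte(rr, prev + 1e-15)
      prev <- rr
    }
  }
  ## expected cases under a strategy never exceed baseline in this mode
  base <- expected_cases(p)
  for (s in strategy_names())
    expect_lte(expected_cases(p, s), base + 1e-9)
})

test_that("strategy name handling", {
  expect_equal(strategy_members("WM-LEV-PPE"), c("WM", "LEV", "PPE"))
  expect_equal(strategy_members(NULL), character())
  expect_error(strategy_members("WM-XYZ"), "unknown strategy")
  expect_length(strategy_names(), 7)
})
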