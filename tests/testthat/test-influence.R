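toy_diagram <- function() {
  influence_diagram(
    chance = list(chance_node("coin", c("heads", "tails"), cpt = c(0.5, 0.5))),
    utility = list(utility_node("payout", parents = "coin", table = c(1, 0)))
  )
}

test_that("enumeration reproduces hand-computable expectations", {
  toy <- toy_diagram()
  expect_equal(expected_value(toy, "payout"), 0.5)
  ## evidence fixing all parents of a utility returns the table entry
  expect_equal(expected_value(toy, "payout", evidence = list(coin = "tails")), 0)
  expect_equal(expected_value(toy, "payout", evidence = list(coin = "heads")), 1)

  ## uncalibrated per-worker lifetime case probability is the risk mixture
  net0 <- build_network(default_parameters())
  expect_equal(expected_value(net0, "lung_cancer_case", decision = "none"),
               0.47 * 9.1e-4 + 0.39 * 1.2e-3 + 0.14 * 1.4e-3,
               tolerance = 1e-12)
})

test_that("built diagram is valid and carries the configured marginals", {
  net <- build_network(calibrated_params())
  expect_length(validate_diagram(net), 0)
  expect_equal(unname(node_marginal(net, "primary_exposure", decision = "none")),
               c(0.47, 0.39, 0.14, 0))
  expect_equal(unname(node_marginal(net, "sex", decision = "none")),
               c(0.7, 0.3))
  ## every node's enumerated marginal sums to 1 for every strategy
  for (d in c("none", strategy_names())) {
    for (nd in names(net$chance)) {
      m <- node_marginal(net, nd, decision = d)
      expect_equal(sum(m), 1, tolerance = 1e-9)
      expect_true(all(m >= -1e-12 & m <= 1 + 1e-12))
    }
  }
})

test_that("diagram-level population quantities agree with the direct pipeline", {
  p <- calibrated_params()
  net <- build_network(p)
  N <- p$workers_total
  ev <- evaluate_all(p)
  for (s in c("WM-LEV", "PPE", "WM-LEV-PPE")) {
    row <- ev[ev$strategy == s, ]
    expect_equal(expected_value(net, "case_averted", decision = s) * N,
                 row$cases_averted, tolerance = 1e-9)
    expect_equal(expected_value(net, "averted_cost", decision = s) * N,
                 row$averted_total, tolerance = 1e-6)
    expect_equal(expected_value(net, "net_benefit", decision = s) * N,
                 row$net_benefit, tolerance = 1e-6)
  }
  expect_equal(expected_value(net, "lung_cancer_case", decision = "none") * N,
               110, tolerance = 1e-9)
})

test_that("validate_diagram reports normalization, parent and cycle violations", {
  bad_row <- influence_diagram(
    chance = list(chance_node("x", c("a", "b"), cpt = c(0.6, 0.6))))
  v <- validate_diagram(bad_row)
  expect_length(v, 1)
  expect_match(v, "node 'x': CPT row 1 sums to 1.2")

  self_edge <- influence_diagram(
    chance = list(chance_node("a", c("y", "n"), parents = "a",
                              cpt = matrix(c(0.5, 0.5, 0.5, 0.5), 2))))
  expect_true(any(grepl("self-edge|cyclic", validate_diagram(self_edge))))

  orphan <- influence_diagram(
    chance = list(chance_node("a", c("y", "n"), parents = "ghost",
                              cpt = c(0.5, 0.5))))
  expect_true(any(grepl("unresolvable parent 'ghost'", validate_diagram(orphan))))
})

test_that("ancestral sampling is deterministic under a seed and state-legal", {
  net <- build_network(calibrated_params())
  s1 <- sample_network(net, 500, seed = 42, decision = "WM-LEV")
  s2 <- sample_network(net, 500, seed = 42, decision = "WM-LEV")
  expect_identical(s1, s2)
  expect_equal(attr(s1, "seed"), 42)

  one <- sample_network(net, 1, seed = 7, decision = "PPE")
  expect_equal(nrow(one), 1)
  for (nd in names(net$chance))
    expect_true(one[[nd]] %in% net$chance[[nd]]$states)

  expect_error(sample_network(net, 0, seed = 1, decision = "PPE"),
               "n must be positive")
  expect_error(sample_network(net, 10, seed = 1), "select a decision")
})

test_that("Monte-Carlo sampling converges to the enumerated expectation", {
  net <- build_network(calibrated_params())
  n <- 2e5
  for (d in c("none", "WM-LEV", "PPE")) {
    s <- sample_network(net, n, seed = 11, decision = d)
    for (target in c("averted_cost", "net_benefit")) {
      exact <- expected_value(net, target, decision = d)
      se <- stats::sd(s[[target]]) / sqrt(n)
      expect_lt(abs(mean(s[[target]]) - exact), max(3 * se, 1e-12))
    }
  }
})

test_that("usage errors for unknown nodes, states and decision evidence", {
  net <- build_network(calibrated_params())
  expect_error(expected_value(net, "no_such_node", decision = "none"),
               "unknown node")
  expect_error(expected_value(net, "net_benefit",
                              evidence = list(sex = "other"),
                              decision = "none"), "unknown state")
  expect_error(expected_value(net, "net_benefit",
                              evidence = list(strategy = "WM"),
                              decision = "none"), "not evidence")
  expect_error(expected_value(net, "net_benefit", decision = "bogus"),
               "unknown decision alternative")
  expect_error(expected_value(net, "sex", decision = "none"),
               "no numeric state values")
})

test_that("diagram serializes to parseable JSON", {
  net <- build_network(calibrated_params())
  js <- diagram_to_json(net)
  parsed <- jsonlite::fromJSON(js, simplifyVector = FALSE)
  expect_setequal(names(parsed$chance), names(net$chance))
  expect_equal(parsed$decision$strategy$alternatives[[2]], "WM-LEV-PPE")
  path <- tempfile(fileext = ".json")
  diagram_to_json(net, path)
  expect_true(file.exists(path))
})
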