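#' Evaluate one intervention strategy
#'
#' Computes the full economic result for one strategy: expected cases
#' averted, averted lifetime case costs by component (cases averted times
#' the expected per-case cost), implementation costs by member
#' intervention, net benefit (averted total minus intervention total) and
#' benefit-cost ratio (averted total over intervention total; `NA` when
#' the intervention cost is zero).
#'
#' @param params a calibrated `silica_params` object.
#' @param strategy a strategy name (see [strategy_names()]), or `NULL` for
#'   the no-intervention baseline (zero averted, zero cost).
#' @param case_cost optional precomputed [expected_case_cost()] breakdown.
#' @return An `evaluation_result` list with elements `strategy`,
#'   `protected_fraction`, `cases_averted`, `averted` (cost breakdown),
#'   `intervention_costs` (named vector), `net_benefit`, `bc_ratio`.
#' @examples
#' p <- calibrate_parameters(default_parameters())
#' evaluate_strategy(p, "WM-LEV")$net_benefit / 1e6   # ~ 105.7
#' @export
evaluate_strategy <- function(params, strategy, case_cost = NULL) {
  if (is.null(case_cost)) case_cost <- expected_case_cost(params)
  alloc <- allocate_protection(strategy, params)
  averted_n <- if (is.null(strategy)) 0 else cases_averted(params, strategy)
  averted <- lapply(case_cost[c("direct", "indirect", "intangible")],
                    function(x) averted_n * x)
  averted$total <- averted$direct + averted$indirect + averted$intangible
  costs <- strategy_cost(strategy, params)
  total_cost <- sum(costs)
  nb <- averted$total - total_cost
  bc <- if (total_cost > 0) averted$total / total_cost else NA_real_
  structure(list(
    strategy = strategy %||% "none",
    protected_fraction = alloc$protected_fraction,
    cases_averted = averted_n,
    averted = averted,
    intervention_costs = costs,
    net_benefit = nb,
    bc_ratio = bc
  ), class = "evaluation_result")
}

## Flatten evaluation_result objects into the reporting data frame
evaluation_table <- function(results) {
  rows <- lapply(results, function(r) {
    cost_of <- function(nm) if (nm %in% names(r$intervention_costs))
      r$intervention_costs[[nm]] else 0
    data.frame(
      strategy = r$strategy,
      protected_fraction = r$protected_fraction,
      cases_averted = r$cases_averted,
      averted_direct = r$averted$direct,
      averted_indirect = r$averted$indirect,
      averted_intangible = r$averted$intangible,
      averted_total = r$averted$total,
      cost_WM = cost_of("WM"),
      cost_LEV = cost_of("LEV"),
      cost_PPE = cost_of("PPE"),
      cost_total = sum(r$intervention_costs),
      net_benefit = r$net_benefit,
      bc_ratio = r$bc_ratio,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Evaluate all seven strategies
#'
#' One [evaluate_strategy()] result per strategy, in the canonical column
#' order, flattened to a data frame.
#'
#' @param params a calibrated `silica_params` object.
#' @return A data frame of class `silica_evaluation`, one row per strategy,
#'   with cases averted, averted cost components and total, per-intervention
#'   and total implementation cost, net benefit and benefit-cost ratio
#'   (money in 2017 CAD).
#' @export
evaluate_all <- function(params) {
  case_cost <- expected_case_cost(params)
  results <- lapply(STRATEGIES, function(s)
    evaluate_strategy(params, s, case_cost = case_cost))
  out <- evaluation_table(results)
  class(out) <- c("silica_evaluation", "data.frame")
  attr(out, "baseline_cases") <- expected_cases(params, NULL)
  attr(out, "baseline_burden") <- expected_cases(params, NULL) * case_cost$total
  out
}

#' One-way sensitivity analysis
#'
#' Re-evaluates the full-coverage strategies (WM-LEV-PPE, WM-LEV, PPE) and
#' the no-intervention baseline while varying a single input:
#'
#' * `workers_total`: alternative workforce sizes (published bounds 46,000
#'   and 118,000);
#' * `exposure_level`: the whole workforce forced into a single exposure
#'   category (probability 1 for that category, calibrated risk scale kept
#'   fixed);
#' * `qaly_value`: alternative QALY monetary values (published range
#'   100,000-200,000).
#'
#' @param params a calibrated `silica_params` object.
#' @param variable one of `"workers_total"`, `"exposure_level"`,
#'   `"qaly_value"`.
#' @param levels vector of levels: numbers for worker counts / QALY values,
#'   category names for `exposure_level`.
#' @return A list of `sensitivity_result` objects, one per level: each has
#'   `scenario` (variable and level), `baseline_cases`, `baseline_burden`,
#'   `results` (evaluation data frame for the three full-coverage
#'   strategies) and `net_benefit_change` (fraction vs the default
#'   parameterization, per strategy).
#' @export
one_way_sensitivity <- function(params, variable, levels) {
  full_cov <- c("WM-LEV-PPE", "WM-LEV", "PPE")
  if (!variable %in% c("workers_total", "exposure_level", "qaly_value"))
    stop(sprintf("usage error: unknown sensitivity variable '%s'", variable),
         call. = FALSE)

  scenario_params <- function(level) {
    p <- params
    if (variable == "workers_total") {
      p$workers_total <- as.numeric(level)
    } else if (variable == "qaly_value") {
      p$econ$qaly_value <- as.numeric(level)
    } else {
      if (!level %in% c("low", "medium", "high"))
        stop(sprintf("usage error: unknown exposure level '%s'", level),
             call. = FALSE)
      p$exposure$probability <- as.numeric(p$exposure$name == level)
    }
    validate_parameters(p)
    p
  }

  default_nb <- {
    ev <- evaluate_all(params)
    setNames(ev$net_benefit, ev$strategy)[full_cov]
  }

  lapply(levels, function(level) {
    p <- scenario_params(level)
    cc <- expected_case_cost(p)
    results <- evaluation_table(lapply(full_cov, function(s)
      evaluate_strategy(p, s, case_cost = cc)))
    nb <- setNames(results$net_benefit, results$strategy)
    structure(list(
      scenario = list(variable = variable, level = level),
      baseline_cases = expected_cases(p, NULL),
      baseline_burden = expected_cases(p, NULL) * cc$total,
      results = results,
      net_benefit_change = nb / default_nb - 1
    ), class = "sensitivity_result")
  })
}
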