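#' Fit the silica intervention cost-benefit model
#'
#' The main entry point. Loads (or takes) a parameter configuration,
#' calibrates it against published aggregate anchors (see
#' [derive_calibration()]), builds the influence diagram, and evaluates all
#' seven intervention strategies. The returned object supports `print()`,
#' `summary()`, `coef()` (calibration constants), `predict()` (strategy
#' results), `simulate()` (Monte-Carlo cohort replicates), `residuals()`
#' (fit vs anchors) and `plot()`.
#'
#' @param config a configuration: path to a YAML/JSON file, a
#'   `silica_params` object, or `NULL` for the shipped defaults.
#' @param anchors calibration anchors (see [default_anchors()]).
#' @param risk_mode `"calibrated_reduction"` (default; reproduces the
#'   anchored aggregates) or `"category_shift"` (mechanistic
#'   concentration-threshold shifting).
#' @return An object of class `silica_cba`.
#' @examples
#' fit <- silica_cba()
#' summary(fit)
#' coef(fit)["risk_scale"]
#' predict(fit, "WM-LEV")
#' @export
silica_cba <- function(config = NULL, anchors = NULL,
                       risk_mode = c("calibrated_reduction",
                                     "category_shift")) {
  risk_mode <- match.arg(risk_mode)
  params <- if (is.null(config)) {
    default_parameters()
  } else if (inherits(config, "silica_params")) {
    config
  } else {
    load_parameters(config)
  }
  params$risk_mode <- risk_mode
  if (is.null(anchors)) anchors <- default_anchors()
  params <- calibrate_parameters(params, anchors = anchors)
  structure(list(
    params = params,
    anchors = anchors,
    evaluation = evaluate_all(params),
    diagram = build_network(params),
    call = match.call()
  ), class = "silica_cba")
}

#' @export
print.silica_cba <- function(x, ...) {
  ev <- x$evaluation
  cat("Silica exposure reduction cost-benefit model (2017 CAD)\n")
  cat(sprintf("  workforce: %s exposed workers; risk mode: %s\n",
              format(x$params$workers_total, big.mark = ","),
              x$params$risk_mode))
  cat(sprintf("  baseline: %.1f expected lung cancer cases, $%.0f M burden\n",
              attr(ev, "baseline_cases"), attr(ev, "baseline_burden") / 1e6))
  best_nb <- ev$strategy[which.max(ev$net_benefit)]
  best_bc <- ev$strategy[which.max(ev$bc_ratio)]
  cat(sprintf("  highest net benefit: %s ($%.1f M); highest B/C ratio: %s (%.1f)\n",
              best_nb, max(ev$net_benefit) / 1e6, best_bc, max(ev$bc_ratio)))
  invisible(x)
}

#' @export
summary.silica_cba <- function(object, ...) {
  structure(list(
    evaluation = object$evaluation,
    calibration = object$params$calibration,
    baseline_cases = attr(object$evaluation, "baseline_cases"),
    baseline_burden = attr(object$evaluation, "baseline_burden")
  ), class = "summary.silica_cba")
}

#' @export
print.summary.silica_cba <- function(x, ...) {
  cat(sprintf("Baseline (no intervention): %.1f cases, $%.1f M\n\n",
              x$baseline_cases, x$baseline_burden / 1e6))
  ev <- x$evaluation
  disp <- data.frame(
    strategy = ev$strategy,
    `protected%` = round(100 * ev$protected_fraction),
    cases_averted = round(ev$cases_averted, 1),
    `averted$M` = round(ev$averted_total / 1e6, 1),
    `cost$M` = round(ev$cost_total / 1e6, 1),
    `net_benefit$M` = round(ev$net_benefit / 1e6, 1),
    `B/C` = round(ev$bc_ratio, 1),
    check.names = FALSE
  )
  print(disp, row.names = FALSE)
  cal <- x$calibration
  cat(sprintf("\nCalibration: risk_scale %.4f, per-case cost $%.0f,\n",
              cal$risk_scale, cal$per_case_cost))
  cat(sprintf("  cost shares %s; risk reductions %s\n",
              paste(sprintf("%s %.3f", names(cal$cost_shares),
                            cal$cost_shares), collapse = ", "),
              paste(sprintf("%s %.3f", names(cal$risk_reduction),
                            cal$risk_reduction), collapse = ", ")))
  invisible(x)
}

#' @export
coef.silica_cba <- function(object, ...) {
  cal <- object$params$calibration
  c(risk_scale = cal$risk_scale,
    per_case_cost = unname(cal$per_case_cost),
    setNames(as.numeric(cal$cost_shares),
             paste0("share_", names(cal$cost_shares))),
    setNames(as.numeric(cal$unit_costs),
             paste0("unit_cost_", names(cal$unit_costs))),
    setNames(as.numeric(cal$risk_reduction),
             paste0("risk_reduction_", names(cal$risk_reduction))))
}

#' Strategy predictions from a fitted model
#'
#' @param object a [silica_cba()] fit.
#' @param strategy optional strategy name(s); all seven when omitted.
#' @param ... unused.
#' @return Rows of the evaluation data frame (money in 2017 CAD).
#' @export
predict.silica_cba <- function(object, strategy = NULL, ...) {
  ev <- object$evaluation
  if (is.null(strategy)) return(ev)
  bad <- setdiff(strategy, ev$strategy)
  if (length(bad))
    stop(sprintf("unknown strategy '%s'", bad[[1]]), call. = FALSE)
  ev[match(strategy, ev$strategy), , drop = FALSE]
}

#' Anchored-quantity residuals of the calibration
#'
#' Differences between the model's fitted aggregates and the published
#' anchors they were calibrated to: baseline cases and burden, cases
#' averted and implementation cost of each single-intervention strategy.
#' All should be numerically zero for an exactly calibrated model.
#'
#' @param object a [silica_cba()] fit.
#' @param ... unused.
#' @return Named numeric vector (cases; money in CAD).
#' @export
residuals.silica_cba <- function(object, ...) {
  ev <- object$evaluation
  a <- object$anchors
  row <- function(s) ev[ev$strategy == s, ]
  c(baseline_cases = attr(ev, "baseline_cases") - a$baseline_cases,
    baseline_burden = attr(ev, "baseline_burden") - a$baseline_burden,
    averted_WM = row("WM")$cases_averted - a$averted_cases[["WM"]],
    averted_LEV = row("LEV")$cases_averted - a$averted_cases[["LEV"]],
    averted_PPE = row("PPE")$cases_averted - a$averted_cases[["PPE"]],
    cost_WM = row("WM")$cost_total - a$intervention_cost[["WM"]],
    cost_LEV = row("LEV")$cost_total - a$intervention_cost[["LEV"]],
    cost_PPE = row("PPE")$cost_total - a$intervention_cost[["PPE"]])
}

#' Monte-Carlo replicates from a fitted model
#'
#' Generates a synthetic cohort of the configured workforce size under
#' `strategy` and simulates `nsim` outcome replicates (see
#' [simulate_outcomes()]).
#'
#' @param object a [silica_cba()] fit.
#' @param nsim number of replicates.
#' @param seed integer seed.
#' @param strategy strategy name or `"none"`.
#' @param n cohort size; defaults to the configured workforce.
#' @param ... unused.
#' @return An `mc_summary` object.
#' @export
simulate.silica_cba <- function(object, nsim = 100, seed = 1L,
                                strategy = "none", n = NULL, ...) {
  params <- object$params
  if (is.null(n)) n <- params$workers_total
  s <- if (identical(strategy, "none")) NULL else strategy
  cohort <- generate_cohort(n, params, strategy = s, seed = seed)
  simulate_outcomes(cohort, params, seed = seed + 1L, reps = nsim)
}

#' Net-benefit and benefit-cost plot
#'
#' Barplots of net benefit (millions, 2017 CAD) and benefit-cost ratio per
#' strategy.
#'
#' @param x a [silica_cba()] fit.
#' @param ... passed to [graphics::barplot()].
#' @return `x`, invisibly.
#' @export
plot.silica_cba <- function(x, ...) {
  ev <- x$evaluation
  old <- graphics::par(mfrow = c(1, 2), mar = c(7, 4, 2, 1))
  on.exit(graphics::par(old))
  graphics::barplot(ev$net_benefit / 1e6, names.arg = ev$strategy, las = 2,
                    ylab = "Net benefit ($M, 2017 CAD)", ...)
  graphics::barplot(ev$bc_ratio, names.arg = ev$strategy, las = 2,
                    ylab = "Benefit-cost ratio", ...)
  graphics::abline(h = 1, lty = 2)
  invisible(x)
}

#' @export
print.mc_summary <- function(x, ...) {
  cat(sprintf("Monte-Carlo summary: %d workers, %d replicates, strategy %s (seed %d)\n",
              x$n_workers, x$reps, x$strategy, x$seed))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
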