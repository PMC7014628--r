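## Segment states of the protection-allocation node, fixed across strategies
SEGMENT_STATES <- c("WM", "LEV", "WM+PPE", "LEV+PPE", "PPE", "none")

#' Build the economic-evaluation influence diagram from a parameter set
#'
#' Constructs the computable influence diagram: chance nodes for worker
#' count class, primary exposure, protection segment, secondary exposure,
#' lung-cancer case, case averted, age, sex, survival, direct cost, QALY
#' value and protection factor; one decision node (the strategy, including
#' the `"none"` comparator); and utility nodes for per-worker averted case
#' cost, per-worker intervention cost, and their difference (net benefit).
#' All utilities are per exposed worker; multiply expectations by
#' `workers_total` for population totals.
#'
#' Continuous quantities (protection factor, direct cost, QALY value) enter
#' the exact-enumeration diagram as degenerate single-state nodes carrying
#' their deterministic value; the Monte-Carlo cohort simulator draws them
#' from their continuous distributions instead.
#'
#' @param params a validated (typically calibrated) `silica_params` object.
#' @return An `influence_diagram`; passes [validate_diagram()] with zero
#'   violations.
#' @examples
#' net <- build_network(calibrate_parameters(default_parameters()))
#' node_marginal(net, "primary_exposure", decision = "none")
#' @export
build_network <- function(params) {
  validate_parameters(params)
  ex <- params$exposure
  econ <- params$econ
  alternatives <- c("none", STRATEGIES)

  seg_cpt <- t(vapply(alternatives, function(a) {
    alloc <- allocate_protection(if (a == "none") NULL else a, params)
    row <- setNames(numeric(length(SEGMENT_STATES)), SEGMENT_STATES)
    row[names(alloc$segments)] <- alloc$segments
    row
  }, numeric(length(SEGMENT_STATES))))

  ## deterministic category shift per (primary, segment); rows ordered with
  ## primary_exposure varying fastest
  sec_grid <- expand.grid(p = seq_len(nrow(ex)), s = seq_along(SEGMENT_STATES))
  sec_cpt <- t(vapply(seq_len(nrow(sec_grid)), function(i) {
    p <- ex$name[sec_grid$p[i]]
    members <- segment_members(SEGMENT_STATES[sec_grid$s[i]])
    new_cat <- if (p == "negligible") "negligible"
      else shift_exposure(p, combined_effectiveness(members, params),
                          params)$category
    as.numeric(ex$name == new_cat)
  }, numeric(nrow(ex))))

  case_prob <- vapply(seq_len(nrow(sec_grid)), function(i) {
    members <- segment_members(SEGMENT_STATES[sec_grid$s[i]])
    segment_case_probability(ex$name[sec_grid$p[i]], members, params)
  }, numeric(1))
  base_prob <- params$calibration$risk_scale *
    ex$lifetime_risk[sec_grid$p]
  averted_prob <- pmax(0, base_prob - case_prob)

  model <- build_lifetime_cost_model(params)
  cost_tab <- profile_cost_table(params, model)
  ## utility rows ordered (case_averted, age, sex, survival), first fastest;
  ## cost_tab rows are (age x sex x survival) in that nesting already
  averted_table <- as.numeric(rbind(
    0, cost_tab$direct + cost_tab$indirect + cost_tab$intangible))

  per_worker_cost <- vapply(SEGMENT_STATES, function(s) {
    members <- segment_members(s)
    if (!length(members)) return(0)
    sum(vapply(members, function(nm) {
      iv <- params$interventions[[nm]]
      uc <- if (is.na(iv$unit_cost)) 0 else iv$unit_cost
      pf <- if (nm == "PPE") 1 else iv$protection_factor_mean
      uc / pf
    }, numeric(1)))
  }, numeric(1))

  n_profile <- length(averted_table)                 # 2 x 13 x 2 x 2 = 104
  nb_table <- as.numeric(outer(averted_table, per_worker_cost, `-`))

  workers_states <- c("lower", "baseline", "upper")
  workers_values <- c(46000, params$workers_total, 118000)

  influence_diagram(
    chance = list(
      chance_node("worker_count", workers_states,
                  cpt = c(0, 1, 0), values = workers_values),
      chance_node("primary_exposure", ex$name, cpt = ex$probability),
      chance_node("protection_segment", SEGMENT_STATES,
                  parents = "strategy", cpt = seg_cpt),
      chance_node("secondary_exposure", ex$name,
                  parents = c("primary_exposure", "protection_segment"),
                  cpt = sec_cpt),
      chance_node("lung_cancer_case", c("no", "yes"),
                  parents = c("primary_exposure", "protection_segment"),
                  cpt = cbind(1 - case_prob, case_prob), values = c(0, 1)),
      chance_node("case_averted", c("no", "yes"),
                  parents = c("primary_exposure", "protection_segment"),
                  cpt = cbind(1 - averted_prob, averted_prob),
                  values = c(0, 1)),
      chance_node("age", age_bin_labels(), cpt = unname(econ$age_probs),
                  values = age_bin_midpoints()),
      chance_node("sex", c("male", "female"), cpt = unname(econ$sex_split)),
      chance_node("survival", c("dies", "survives"),
                  cpt = c(1 - econ$survival_probability,
                          econ$survival_probability), values = c(0, 1)),
      chance_node("direct_cost", "expected", cpt = 1,
                  values = model$direct_per_case),
      chance_node("qaly_value", "baseline", cpt = 1,
                  values = econ$qaly_value),
      chance_node("protection_factor", "mean", cpt = 1,
                  values = params$interventions$WM$protection_factor_mean)
    ),
    decision = list(decision_node("strategy", alternatives)),
    utility = list(
      utility_node("averted_cost",
                   parents = c("case_averted", "age", "sex", "survival"),
                   table = averted_table),
      utility_node("intervention_cost", parents = "protection_segment",
                   table = per_worker_cost),
      utility_node("net_benefit",
                   parents = c("case_averted", "age", "sex", "survival",
                               "protection_segment"),
                   table = nb_table)
    )
  )
}
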