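## Truncated normal sampler by inverse-CDF (used for protection factors)
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd <= 0) return(rep(mean, n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

with_seed <- function(seed, expr) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic worker cohort
#'
#' Draws `n` silica-exposed workers with exposure categories from the
#' configured multinomial distribution, assigns each worker to an
#' intervention segment according to the strategy's coverage allocation,
#' and draws a one-shot lifetime lung-cancer indicator at each worker's
#' residual risk (a single Bernoulli per worker: the model is a lifetime
#' expectation, not a time-stepped cohort).
#'
#' @param n number of workers (>= 0).
#' @param params a (typically calibrated) `silica_params` object.
#' @param strategy strategy name or `NULL` for the baseline.
#' @param seed integer seed; identical seeds give identical cohorts.
#' @return Data frame with columns `id`, `exposure`, `protected_by`
#'   (segment label), `risk_baseline`, `risk_residual`, `sampled_case`;
#'   the strategy is recorded in attribute `"strategy"`.
#' @export
generate_cohort <- function(n, params, strategy = NULL, seed = 1L) {
  if (n < 0) stop("usage error: n must be >= 0", call. = FALSE)
  ex <- params$exposure
  alloc <- allocate_protection(strategy, params)
  if (n == 0) {
    out <- data.frame(id = integer(0), exposure = character(0),
                      protected_by = character(0),
                      risk_baseline = numeric(0), risk_residual = numeric(0),
                      sampled_case = logical(0), stringsAsFactors = FALSE)
    attr(out, "strategy") <- alloc$strategy
    attr(out, "seed") <- seed
    return(out)
  }
  risk <- residual_risk_matrix(params)
  with_seed(seed, {
    exposure <- sample(ex$name, n, replace = TRUE, prob = ex$probability)
    segment <- sample(names(alloc$segments), n, replace = TRUE,
                      prob = alloc$segments)
    p0 <- risk[cbind(exposure, "none")]
    p1 <- risk[cbind(exposure, segment)]
    out <- data.frame(
      id = seq_len(n),
      exposure = exposure,
      protected_by = segment,
      risk_baseline = unname(p0),
      risk_residual = unname(p1),
      sampled_case = if (n) stats::rbinom(n, 1, p1) == 1 else logical(0),
      stringsAsFactors = FALSE
    )
    attr(out, "strategy") <- alloc$strategy
    attr(out, "seed") <- seed
    out
  })
}

## Residual lifetime risk per (exposure category x segment), incl. "none"
residual_risk_matrix <- function(params) {
  ex <- params$exposure
  segs <- unique(c(SEGMENT_STATES, "none"))
  m <- matrix(0, nrow(ex), length(segs), dimnames = list(ex$name, segs))
  for (s in segs) {
    members <- segment_members(s)
    m[, s] <- vapply(ex$name, segment_case_probability,
                     numeric(1), members = members, params = params)
  }
  m
}

## Units needed for `n_protected` workers when each deployed unit protects a
## truncated-Gaussian number of workers (renewal count).
units_needed <- function(n_protected, iv) {
  if (n_protected <= 0) return(0L)
  mu <- iv$protection_factor_mean
  draw <- ceiling(n_protected / mu * 1.1) + 50
  pf <- rtruncnorm(draw, mu, iv$protection_factor_sd,
                   iv$protection_factor_range[1], iv$protection_factor_range[2])
  cum <- cumsum(pf)
  while (cum[length(cum)] < n_protected) {
    extra <- rtruncnorm(draw, mu, iv$protection_factor_sd,
                        iv$protection_factor_range[1],
                        iv$protection_factor_range[2])
    cum <- c(cum, cum[length(cum)] + cumsum(extra))
  }
  sum(cum < n_protected) + 1L
}

#' Monte-Carlo simulation of cohort outcomes
#'
#' The stochastic counterpart of the enumerated expectations. For each
#' replicate: lifetime case indicators are drawn at each worker's residual
#' risk (aggregated as exact binomial draws within
#' exposure-category-by-segment cells, which is distributionally identical
#' to per-worker Bernoulli draws); averted cases are drawn at the
#' baseline-minus-residual risk; each case and each averted case receives a
#' profile from
#' the age/sex/survival distribution with its lifetime cost (Gaussian
#' direct-cost noise, truncated at zero); intervention costs deploy units
#' whose protection factors are truncated-Gaussian draws, counting the
#' units needed to cover the protected headcount. Means and
#' normal-approximation confidence intervals are computed across
#' replicates.
#'
#' @param cohort a [generate_cohort()] data frame.
#' @param params the `silica_params` object used to generate the cohort.
#' @param seed integer seed.
#' @param reps number of replicates (>= 1).
#' @return An object of class `mc_summary`: list with `replicates` (one row
#'   per replicate: cases, cases_averted, averted_cost, intervention_cost,
#'   net_benefit, male_fraction, survivor_fraction) and `summary` (mean,
#'   sd, standard error and 95% CI per quantity), plus the seed and
#'   strategy.
#' @export
simulate_outcomes <- function(cohort, params, seed = 1L, reps = 100L) {
  if (reps < 1) stop("usage error: reps must be >= 1", call. = FALSE)
  strategy <- attr(cohort, "strategy") %||% "none"
  members <- strategy_members(if (strategy == "none") NULL else strategy)

  cells <- stats::aggregate(
    list(n = cohort$id),
    by = list(p0 = cohort$risk_baseline, p1 = cohort$risk_residual),
    FUN = length)
  seg_counts <- table(cohort$protected_by)
  n_protected <- vapply(members, function(nm) {
    has <- vapply(names(seg_counts), function(s) nm %in% segment_members(s),
                  logical(1))
    sum(seg_counts[has])
  }, numeric(1))

  model <- build_lifetime_cost_model(params)
  cost_tab <- profile_cost_table(params, model)
  fixed_cost <- cost_tab$indirect + cost_tab$intangible
  w <- cost_tab$weight
  cv <- params$econ$direct_cost_cv

  with_seed(seed, {
    rows <- lapply(seq_len(reps), function(rep) {
      cases <- sum(stats::rbinom(nrow(cells), cells$n, cells$p1))
      m <- sum(stats::rbinom(nrow(cells), cells$n,
                             pmax(0, cells$p0 - cells$p1)))
      if (cases > 0) {               # profiles of the cases that occur
        cprof <- sample.int(nrow(cost_tab), cases, replace = TRUE, prob = w)
        male_frac <- mean(cost_tab$sex[cprof] == "male")
        surv_frac <- mean(cost_tab$survives[cprof])
      } else {
        male_frac <- NA_real_
        surv_frac <- NA_real_
      }
      if (m > 0) {                   # profiles and costs of averted cases
        prof <- sample.int(nrow(cost_tab), m, replace = TRUE, prob = w)
        direct <- pmax(0, stats::rnorm(m, cost_tab$direct[prof],
                                       cv * cost_tab$direct[prof]))
        averted_cost <- sum(fixed_cost[prof]) + sum(direct)
      } else {
        averted_cost <- 0
      }
      icost <- 0
      for (nm in members) {
        iv <- params$interventions[[nm]]
        icost <- icost + if (nm == "PPE") {
          iv$unit_cost * n_protected[[nm]]
        } else {
          iv$unit_cost * units_needed(n_protected[[nm]], iv)
        }
      }
      c(cases = cases, cases_averted = m, averted_cost = averted_cost,
        intervention_cost = icost, net_benefit = averted_cost - icost,
        male_fraction = male_frac, survivor_fraction = surv_frac)
    })
    repdf <- as.data.frame(do.call(rbind, rows))
    qty <- c("cases", "cases_averted", "averted_cost", "intervention_cost",
             "net_benefit")
    summ <- do.call(rbind, lapply(qty, function(q) {
      x <- repdf[[q]]
      se <- stats::sd(x) / sqrt(length(x))
      data.frame(quantity = q, mean = mean(x), sd = stats::sd(x), se = se,
                 ci_lower = mean(x) - 1.96 * se,
                 ci_upper = mean(x) + 1.96 * se,
                 stringsAsFactors = FALSE)
    }))
    structure(list(replicates = repdf, summary = summ,
                   male_fraction = mean(repdf$male_fraction, na.rm = TRUE),
                   survivor_fraction = mean(repdf$survivor_fraction,
                                            na.rm = TRUE),
                   strategy = strategy, seed = seed, reps = reps,
                   n_workers = nrow(cohort)),
              class = "mc_summary")
  })
}
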