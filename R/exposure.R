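## The seven intervention strategies, in published column order
STRATEGIES <- c("WM-LEV-PPE", "WM-LEV", "WM-PPE", "WM", "LEV-PPE", "LEV", "PPE")

#' The seven intervention strategies
#'
#' @return Character vector of strategy names, in the canonical reporting
#'   order (all-intervention first, PPE-only last).
#' @export
strategy_names <- function() STRATEGIES

#' Member interventions of a strategy
#'
#' @param strategy a strategy name, e.g. `"WM-LEV"`, or `NULL`/`"none"` for
#'   the no-intervention baseline.
#' @return Character vector of member interventions (subset of WM, LEV, PPE);
#'   empty for the baseline.
#' @export
strategy_members <- function(strategy) {
  if (is.null(strategy) || identical(strategy, "none")) return(character())
  if (!strategy %in% STRATEGIES)
    stop(sprintf("unknown strategy '%s'", strategy), call. = FALSE)
  strsplit(strategy, "-", fixed = TRUE)[[1]]
}

## Segment labels: which intervention layers protect a worker.
segment_label <- function(members) {
  if (!length(members)) "none" else paste(members, collapse = "+")
}

segment_members <- function(segment) {
  if (identical(segment, "none")) character()
  else strsplit(segment, "+", fixed = TRUE)[[1]]
}

#' Partition the workforce into intervention segments for a strategy
#'
#' The group-level interventions cover complementary occupation groups: WM
#' applies to 60% of exposed workers and LEV to a disjoint 40% (so WM-LEV
#' protects everyone), while PPE overlays the whole workforce whenever it is
#' a member. The unprotected remainder is an explicit `"none"` segment.
#'
#' @param strategy a strategy name or `NULL` for the baseline.
#' @param params a validated `silica_params` object.
#' @return An object of class `strategy_allocation`: list with `segments`
#'   (named fractions over the whole workforce, summing to 1) and
#'   `protected_fraction`.
#' @examples
#' allocate_protection("WM", default_parameters())$segments    # WM .6, none .4
#' @export
allocate_protection <- function(strategy, params) {
  members <- strategy_members(strategy)
  cov_wm <- params$interventions$WM$coverage
  cov_lev <- params$interventions$LEV$coverage
  has <- function(x) x %in% members
  ppe <- if (has("PPE")) "PPE" else NULL

  slices <- list()
  add <- function(slices, layer_members, frac) {
    if (frac <= 0) return(slices)
    lab <- segment_label(layer_members)
    slices[[lab]] <- (slices[[lab]] %||% 0) + frac
    slices
  }
  used <- 0
  if (has("WM")) {
    slices <- add(slices, c("WM", ppe), cov_wm)
    used <- used + cov_wm
  }
  if (has("LEV")) {
    slices <- add(slices, c("LEV", ppe), cov_lev)
    used <- used + cov_lev
  }
  remainder <- 1 - used
  if (remainder < -1e-9)
    stop("coverage slices exceed the workforce", call. = FALSE)
  remainder <- max(remainder, 0)
  slices <- add(slices, ppe, remainder)        # PPE-only slice, or unprotected
  if (!length(slices)) slices <- list(none = 1)

  segments <- unlist(slices)
  protected <- sum(segments[names(segments) != "none"])
  structure(list(strategy = strategy %||% "none",
                 segments = segments,
                 protected_fraction = protected),
            class = "strategy_allocation")
}

#' Combined effectiveness of stacked intervention layers
#'
#' Field effectiveness of each layer is its reported effectiveness times the
#' field factor; layers combine through multiplicative residual exposure,
#' `1 - prod(1 - e_i)`, which keeps the combination bounded in \[0, 1\].
#'
#' @param members character vector of intervention names.
#' @param params a validated `silica_params` object.
#' @return A single effectiveness in \[0, 1\] (0 for no members).
#' @export
combined_effectiveness <- function(members, params) {
  if (!length(members)) return(0)
  e <- vapply(members, function(nm) {
    iv <- params$interventions[[nm]]
    iv$reported_effectiveness * iv$field_factor
  }, numeric(1))
  1 - prod(1 - e)
}

#' Post-intervention exposure category (category-shift mechanism)
#'
#' An intervention with combined effectiveness `e` multiplies the
#' representative concentration of a worker's category by `1 - e`; the
#' result is re-classified by the 0.0125 / 0.025 mg/m^3 thresholds. The
#' representative concentration is the category upper bound for low and
#' medium; the open-ended high category uses its lower bound 0.025 mg/m^3.
#'
#' @param category an exposure category name (`low`, `medium`, `high`).
#' @param combined_effectiveness effectiveness in \[0, 1\].
#' @param params a validated `silica_params` object.
#' @return List with `category` (post-intervention name) and `residual_risk`
#'   (scaled lifetime risk of the new category).
#' @examples
#' # WM alone (0.82 x 0.75 = 0.615) moves "high" down to "low":
#' shift_exposure("high", 0.615, default_parameters())$category
#' @export
shift_exposure <- function(category, combined_effectiveness,
                           params = default_parameters()) {
  if (combined_effectiveness < 0 || combined_effectiveness > 1)
    stop("effectiveness must lie in [0, 1]", call. = FALSE)
  ex <- params$exposure
  i <- match(category, ex$name)
  if (is.na(i)) stop(sprintf("unknown exposure category '%s'", category),
                     call. = FALSE)
  if (category == "negligible")
    return(list(category = "negligible", residual_risk = 0))
  if (combined_effectiveness == 0) {      # identity: no layers, no shift
    risk <- params$calibration$risk_scale * ex$lifetime_risk[i]
    return(list(category = category, residual_risk = risk))
  }
  rep_conc <- if (is.finite(ex$upper[i])) ex$upper[i] else ex$lower[i]
  conc <- rep_conc * (1 - combined_effectiveness)
  new_cat <- if (conc < 0.0125) "low" else if (conc <= 0.025) "medium" else "high"
  j <- match(new_cat, ex$name)
  risk <- params$calibration$risk_scale * ex$lifetime_risk[j]
  primary <- params$calibration$risk_scale * ex$lifetime_risk[i]
  list(category = new_cat, residual_risk = min(risk, primary))
}

## Per-worker lifetime case probability for one exposure category under a
## set of protecting layers, in the configured risk mode.
segment_case_probability <- function(category, members, params) {
  ex <- params$exposure
  i <- match(category, ex$name)
  base <- params$calibration$risk_scale * ex$lifetime_risk[i]
  if (!length(members)) return(base)
  if (params$risk_mode == "calibrated_reduction") {
    resid <- prod(vapply(members, function(nm)
      1 - params$interventions[[nm]]$calibrated_risk_reduction, numeric(1)))
    base * resid
  } else if (params$risk_mode == "category_shift") {
    e <- combined_effectiveness(members, params)
    shift_exposure(category, e, params)$residual_risk
  } else {
    stop(sprintf("unknown risk_mode '%s'", params$risk_mode), call. = FALSE)
  }
}

## Expected per-worker case probability under a strategy (mixture over
## exposure categories and allocation segments).
per_worker_case_probability <- function(params, strategy = NULL) {
  alloc <- allocate_protection(strategy, params)
  ex <- params$exposure
  total <- 0
  for (seg in names(alloc$segments)) {
    frac <- alloc$segments[[seg]]
    members <- segment_members(seg)
    p_seg <- sum(vapply(seq_len(nrow(ex)), function(i) {
      ex$probability[i] * segment_case_probability(ex$name[i], members, params)
    }, numeric(1)))
    total <- total + frac * p_seg
  }
  total
}

#' Expected lung-cancer cases under a strategy
#'
#' Expected cases are workers times lifetime case probability, summed over
#' allocation segments: each segment contributes its worker count times the
#' exposure-mixture case probability after its intervention layers. With no
#' strategy the probability is `risk_scale x sum_c p_c r_c`. In
#' `calibrated_reduction` mode a segment's probability is the baseline
#' probability times the product over member interventions of one minus the
#' calibrated single-intervention risk reduction; in `category_shift` mode
#' layers shift the exposure category by their combined effectiveness.
#'
#' @param params a (typically calibrated) `silica_params` object.
#' @param strategy a strategy name or `NULL` for the no-intervention baseline.
#' @return Expected number of cases (not rounded).
#' @examples
#' p <- calibrate_parameters(default_parameters())
#' expected_cases(p)            # 110 at the calibrated baseline
#' expected_cases(p, "WM-LEV")  # 15 residual cases
#' @export
expected_cases <- function(params, strategy = NULL) {
  if (params$risk_mode == "calibrated_reduction" &&
      !isTRUE(params$calibration$calibrated) && !is.null(strategy) &&
      length(strategy_members(strategy)))
    warning("risk_mode is 'calibrated_reduction' but parameters are not ",
            "calibrated; risk reductions default to 0", call. = FALSE)
  params$workers_total * per_worker_case_probability(params, strategy)
}

#' Expected lung-cancer cases averted by a strategy
#'
#' Baseline expected cases minus expected cases under the strategy; floored
#' at zero.
#'
#' @inheritParams expected_cases
#' @return Expected cases averted.
#' @export
cases_averted <- function(params, strategy) {
  max(0, expected_cases(params, NULL) - expected_cases(params, strategy))
}
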