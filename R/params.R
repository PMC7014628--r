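#' @keywords internal
#' @importFrom stats setNames
"_PACKAGE"

## Canonical orderings used throughout the package
EXPOSURE_LEVELS <- c("low", "medium", "high", "negligible")
INTERVENTIONS <- c("WM", "LEV", "PPE")

#' Labels of the 13 five-year age intervals (25 to 85+)
#'
#' @return Character vector of length 13.
#' @export
age_bin_labels <- function() {
  c(paste(seq(25, 80, by = 5), seq(29, 84, by = 5), sep = "-"), "85+")
}

## Bin midpoints used when a representative age is needed (85+ -> 87)
age_bin_midpoints <- function() {
  c(seq(27, 82, by = 5), 87)
}

## Discretized unimodal age distribution of incident cases, mode at 70-74
## (bin 10 of 13); spread chosen to give a realistic old-age concentration.
default_age_probs <- function() {
  w <- stats::dnorm(seq_len(13), mean = 10, sd = 2.5)
  p <- w / sum(w)
  names(p) <- age_bin_labels()
  p
}

#' Default model parameter set
#'
#' Builds the shipped baseline configuration: 91,000 silica-exposed
#' construction workers; exposure-category probabilities 0.47/0.39/0.14
#' (low/medium/high) with lifetime lung-cancer risks 9.1e-4/1.2e-3/1.4e-3;
#' wet method (WM), local exhaust ventilation (LEV) and personal protective
#' equipment (PPE) interventions with reported effectiveness 0.82/0.93/0.90,
#' a 0.75 field factor, coverages 0.60/0.40/1.00, and a workers-per-unit
#' protection factor of 5 (range 1-10, Gaussian) for the group-level
#' interventions; economic parameters (QALY value $150,000, 3% discount
#' rate, 14% payroll loading, 0.77 post-treatment participation, 0.09
#' survival, 0.7/0.3 male/female split, 13 age bins peaked at 70-74).
#' All monetary values are 2017 Canadian dollars.
#'
#' Calibration constants default to the identity (risk scale 1, zero risk
#' reductions, unit costs unset); see [derive_calibration()] and
#' [calibrate_parameters()].
#'
#' @return A validated object of class `silica_params`.
#' @export
default_parameters <- function() {
  params <- list(
    workers_total = 91000,
    exposure = data.frame(
      name = EXPOSURE_LEVELS,
      lower = c(0, 0.0125, 0.025, 0),
      upper = c(0.0125, 0.025, Inf, 0),
      probability = c(0.47, 0.39, 0.14, 0),
      lifetime_risk = c(9.1e-4, 1.2e-3, 1.4e-3, 0),
      stringsAsFactors = FALSE
    ),
    interventions = list(
      WM = list(name = "WM", reported_effectiveness = 0.82, field_factor = 0.75,
                coverage = 0.60, unit_cost = NA_real_,
                protection_factor_mean = 5, protection_factor_range = c(1, 10),
                protection_factor_sd = 1.5, calibrated_risk_reduction = 0),
      LEV = list(name = "LEV", reported_effectiveness = 0.93, field_factor = 0.75,
                 coverage = 0.40, unit_cost = NA_real_,
                 protection_factor_mean = 5, protection_factor_range = c(1, 10),
                 protection_factor_sd = 1.5, calibrated_risk_reduction = 0),
      PPE = list(name = "PPE", reported_effectiveness = 0.90, field_factor = 0.75,
                 coverage = 1.00, unit_cost = NA_real_,
                 protection_factor_mean = 1, protection_factor_range = c(1, 1),
                 protection_factor_sd = 0, calibrated_risk_reduction = 0)
    ),
    econ = list(
      qaly_value = 150000,
      discount_rate = 0.03,
      payroll_loading = 0.14,
      participation_after_treatment = 0.77,
      survival_probability = 0.09,
      sex_split = c(male = 0.7, female = 0.3),
      age_probs = default_age_probs(),
      home_production_value = 15000,
      quality_weight = 0.83,
      survivor_morbidity_qaly = 1.0,
      direct_cost_cv = 0.2,
      retirement_age = 65,
      currency_year = 2017
    ),
    calibration = empty_calibration(),
    risk_mode = "calibrated_reduction"
  )
  class(params) <- "silica_params"
  validate_parameters(params)
  params
}

empty_calibration <- function() {
  list(
    risk_scale = 1,
    per_case_cost = NA_real_,
    cost_shares = c(direct = NA_real_, indirect = NA_real_, intangible = NA_real_),
    unit_costs = c(WM = NA_real_, LEV = NA_real_, PPE = NA_real_),
    risk_reduction = c(WM = 0, LEV = 0, PPE = 0),
    qaly_at_calibration = NA_real_,
    cost_model_scales = c(direct_per_case = NA_real_,
                          scale_indirect = NA_real_,
                          scale_intangible = NA_real_),
    calibrated = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_validation <- function(...) stop(sprintf(...), call. = FALSE)

check_prob <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1))
    stop_validation("validation error: %s must be a probability in [0, 1]", what)
}

#' Validate a parameter set
#'
#' Checks every structural invariant of the configuration: exposure-category
#' probabilities over low/medium/high sum to 1, lifetime risks non-decreasing
#' in category order, intervention fractions in \[0, 1\], non-negative money
#' and counts, protection factor mean within its range (PPE fixed at 1),
#' sex and age probabilities summing to 1, positive QALY value, and legal
#' risk mode. Calibration constants, when present, must have positive
#' per-case cost and cost shares summing to 1.
#'
#' @param params an object as produced by [default_parameters()] or
#'   [load_parameters()].
#' @param tol tolerance for probability sums.
#' @return `params`, invisibly, if valid; otherwise an error describing the
#'   first violated invariant.
#' @export
validate_parameters <- function(params, tol = 1e-6) {
  req <- c("workers_total", "exposure", "interventions", "econ",
           "calibration", "risk_mode")
  missing_key <- setdiff(req, names(params))
  if (length(missing_key))
    stop_validation("schema error: missing required key '%s'", missing_key[[1]])

  if (!is.numeric(params$workers_total) || params$workers_total <= 0)
    stop_validation("validation error: workers_total must be a positive count")

  ex <- params$exposure
  if (!identical(sort(ex$name), sort(EXPOSURE_LEVELS)))
    stop_validation("schema error: exposure categories must be exactly %s",
                    paste(EXPOSURE_LEVELS, collapse = ", "))
  check_prob(ex$probability, "exposure probability")
  core <- ex[match(c("low", "medium", "high"), ex$name), ]
  if (abs(sum(core$probability) - 1) > tol)
    stop_validation(
      "validation error: exposure probabilities over low/medium/high sum to %.6f, not 1",
      sum(core$probability))
  if (any(ex$lifetime_risk < 0))
    stop_validation("validation error: lifetime risks must be non-negative")
  if (is.unsorted(core$lifetime_risk))
    stop_validation("validation error: lifetime risk must be non-decreasing low <= medium <= high")

  if (!identical(sort(names(params$interventions)), sort(INTERVENTIONS)))
    stop_validation("schema error: interventions must be exactly WM, LEV, PPE")
  for (iv in params$interventions) {
    check_prob(iv$reported_effectiveness, paste(iv$name, "effectiveness"))
    check_prob(iv$field_factor, paste(iv$name, "field factor"))
    check_prob(iv$coverage, paste(iv$name, "coverage"))
    check_prob(iv$calibrated_risk_reduction, paste(iv$name, "risk reduction"))
    if (!is.na(iv$unit_cost) && iv$unit_cost < 0)
      stop_validation("validation error: %s unit cost is negative", iv$name)
    rng <- iv$protection_factor_range
    if (iv$protection_factor_mean < rng[1] || iv$protection_factor_mean > rng[2])
      stop_validation("validation error: %s protection factor mean outside its range", iv$name)
    if (iv$name == "PPE" && iv$protection_factor_mean != 1)
      stop_validation("validation error: PPE protection factor must be 1")
  }

  ec <- params$econ
  if (!is.numeric(ec$qaly_value) || ec$qaly_value <= 0)
    stop_validation("validation error: qaly_value must be positive")
  if (ec$discount_rate < 0)
    stop_validation("validation error: discount_rate must be non-negative")
  check_prob(ec$payroll_loading, "payroll loading")
  check_prob(ec$participation_after_treatment, "participation")
  check_prob(ec$survival_probability, "survival probability")
  check_prob(ec$sex_split, "sex split")
  if (abs(sum(ec$sex_split) - 1) > tol)
    stop_validation("validation error: sex probabilities sum to %.6f, not 1",
                    sum(ec$sex_split))
  if (length(ec$age_probs) != 13)
    stop_validation("schema error: age_probs must have 13 intervals (25 to 85+)")
  check_prob(ec$age_probs, "age probability")
  if (abs(sum(ec$age_probs) - 1) > tol)
    stop_validation("validation error: age probabilities sum to %.6f, not 1",
                    sum(ec$age_probs))
  if (ec$home_production_value < 0)
    stop_validation("validation error: home_production_value is negative")

  cal <- params$calibration
  if (isTRUE(cal$calibrated)) {
    if (!is.finite(cal$per_case_cost) || cal$per_case_cost <= 0)
      stop_validation("validation error: calibrated per_case_cost must be positive")
    if (abs(sum(cal$cost_shares) - 1) > tol)
      stop_validation("validation error: cost shares sum to %.6f, not 1",
                      sum(cal$cost_shares))
    if (any(cal$risk_reduction < 0 | cal$risk_reduction > 1))
      stop_validation("validation error: calibrated risk reductions must lie in [0, 1]")
  }
  if (cal$risk_scale <= 0)
    stop_validation("validation error: risk_scale must be positive")

  if (!params$risk_mode %in% c("calibrated_reduction", "category_shift"))
    stop_validation("validation error: unknown risk_mode '%s'", params$risk_mode)

  invisible(params)
}

#' Load a parameter configuration from YAML or JSON
#'
#' Reads a configuration file mirroring the structure documented in
#' `inst/extdata/config_schema.yaml`, fills defaults for omitted calibration
#' constants (identity risk scale, zero risk reductions, with a warning),
#' and validates every invariant before returning.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return A validated `silica_params` object.
#' @examples
#' cfg <- system.file("extdata", "default_config.yaml", package = "silicaCBA")
#' p <- load_parameters(cfg)
#' p$workers_total
#' @export
load_parameters <- function(path) {
  if (!file.exists(path))
    stop_validation("schema error: configuration file '%s' does not exist", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  params_from_list(raw)
}

## Build a silica_params object from a plain nested list (parsed YAML/JSON)
params_from_list <- function(raw) {
  base <- default_parameters()

  for (key in c("workers_total", "risk_mode"))
    if (!is.null(raw[[key]])) base[[key]] <- raw[[key]]

  if (is.null(raw$exposure))
    stop_validation("schema error: missing required key 'exposure'")
  if (is.data.frame(raw$exposure))   # JSON record arrays simplify to a frame
    raw$exposure <- lapply(seq_len(nrow(raw$exposure)), function(i)
      as.list(raw$exposure[i, ]))
  ex <- base$exposure
  for (cat in raw$exposure) {
    if (is.null(cat$name))
      stop_validation("schema error: missing required key 'exposure$name'")
    i <- match(cat$name, ex$name)
    if (is.na(i))
      stop_validation("schema error: unknown exposure category '%s'", cat$name)
    for (f in c("lower", "upper", "probability", "lifetime_risk"))
      if (!is.null(cat[[f]])) ex[[f]][i] <- as.numeric(cat[[f]])
  }
  ex$upper[is.na(ex$upper) | ex$upper > 1e300] <- Inf  # open-ended high category
  base$exposure <- ex

  if (is.null(raw$interventions))
    stop_validation("schema error: missing required key 'interventions'")
  for (nm in names(raw$interventions)) {
    if (!nm %in% INTERVENTIONS)
      stop_validation("schema error: unknown intervention '%s'", nm)
    for (f in names(raw$interventions[[nm]])) {
      if (!f %in% names(base$interventions[[nm]]))
        stop_validation("schema error: unknown intervention field '%s'", f)
      val <- raw$interventions[[nm]][[f]]
      if (f != "name") val <- as.numeric(unlist(val))
      base$interventions[[nm]][[f]] <- val
    }
  }

  if (!is.null(raw$econ)) {
    for (f in names(raw$econ)) {
      if (!f %in% names(base$econ))
        stop_validation("schema error: unknown econ field '%s'", f)
      val <- raw$econ[[f]]
      if (f %in% c("sex_split", "age_probs")) {
        val <- unlist(val)
        if (f == "sex_split") val <- val[c("male", "female")]
      }
      base$econ[[f]] <- val
    }
    if (!is.null(raw$econ$age_probs)) names(base$econ$age_probs) <- age_bin_labels()
  }

  if (is.null(raw$calibration)) {
    warning("no calibration constants in configuration; using identity defaults ",
            "(risk_scale = 1, zero risk reductions)", call. = FALSE)
  } else {
    cal <- base$calibration
    for (f in names(raw$calibration)) {
      if (!f %in% names(cal))
        stop_validation("schema error: unknown calibration field '%s'", f)
      val <- raw$calibration[[f]]
      if (f %in% c("cost_shares", "unit_costs", "risk_reduction",
                   "cost_model_scales")) {
        v <- setNames(rep(NA_real_, length(cal[[f]])), names(cal[[f]]))
        got <- unlist(val)                       # JSON nulls drop out here
        if (length(got))
          v[names(got)] <- suppressWarnings(as.numeric(got))
        val <- v
      } else if (f != "calibrated") {
        val <- if (is.null(val) || !length(val)) NA_real_
               else suppressWarnings(as.numeric(val))
      }
      cal[[f]] <- val
    }
    base$calibration <- cal
    if (isTRUE(cal$calibrated)) {
      for (nm in INTERVENTIONS) {
        base$interventions[[nm]]$unit_cost <- unname(cal$unit_costs[[nm]])
        base$interventions[[nm]]$calibrated_risk_reduction <-
          unname(cal$risk_reduction[[nm]])
      }
    }
  }

  class(base) <- "silica_params"
  validate_parameters(base)
  base
}

#' Write a parameter set to YAML or JSON
#'
#' Serializes a `silica_params` object so that [load_parameters()] of the
#' written file reproduces an equal parameter set (round-trip property).
#'
#' @param params a validated `silica_params` object.
#' @param path output path; format chosen by extension (`.json` vs YAML).
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  validate_parameters(params)
  out <- list(
    workers_total = params$workers_total,
    risk_mode = params$risk_mode,
    exposure = lapply(seq_len(nrow(params$exposure)), function(i) {
      row <- params$exposure[i, ]
      out <- list(name = row$name, lower = row$lower, upper = row$upper,
                  probability = row$probability,
                  lifetime_risk = row$lifetime_risk)
      if (!is.finite(row$upper)) out$upper <- NULL  # open-ended category
      out
    }),
    interventions = lapply(params$interventions, function(iv) {
      iv$unit_cost <- if (is.na(iv$unit_cost)) NULL else iv$unit_cost
      iv
    }),
    econ = params$econ,
    calibration = params$calibration
  )
  out$econ$sex_split <- as.list(params$econ$sex_split)
  out$econ$age_probs <- unname(params$econ$age_probs)
  out$calibration$cost_shares <- as.list(params$calibration$cost_shares)
  out$calibration$unit_costs <- as.list(params$calibration$unit_costs)
  out$calibration$risk_reduction <- as.list(params$calibration$risk_reduction)
  out$calibration$cost_model_scales <-
    as.list(params$calibration$cost_model_scales)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null")
  } else {
    yaml::write_yaml(out, path, precision = 15)
  }
  invisible(path)
}
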