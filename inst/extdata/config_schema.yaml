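# Configuration schema for silicaCBA parameter files (YAML or JSON).
# Every key, its unit, and its shipped default. Probabilities are decimals
# (never percents); money is in 2017 Canadian dollars.

workers_total:            # count of silica-exposed construction workers; default 91000
risk_mode:                # "calibrated_reduction" (default) or "category_shift"

exposure:                 # list of four categories: low, medium, high, negligible
  - name:                 # category label
    lower:                # concentration lower bound, mg/m^3 (low 0, medium 0.0125, high 0.025)
    upper:                # concentration upper bound, mg/m^3; omit for the open-ended high category
    probability:          # fraction of exposed workers in this category; low/medium/high
                          # must sum to 1 (defaults 0.47 / 0.39 / 0.14; negligible 0)
    lifetime_risk:        # lifetime lung-cancer probability per worker
                          # (defaults 9.1e-4 / 1.2e-3 / 1.4e-3; negligible 0)

interventions:            # exactly WM, LEV, PPE
  WM:
    reported_effectiveness:   # best reported exposure reduction, fraction (0.82)
    field_factor:             # fraction of reported effectiveness achieved in the
                              # field (0.75); field effectiveness = product
    coverage:                 # fraction of workers the intervention applies to (0.60)
    unit_cost:                # 2017 CAD per deployed unit; filled by calibration
    protection_factor_mean:   # workers protected per unit (5; PPE must be 1)
    protection_factor_range:  # [min, max] workers per unit ([1, 10])
    protection_factor_sd:     # Gaussian spread, workers (1.5; chosen so the
                              # range holds ~99.9% of mass before truncation)
    calibrated_risk_reduction: # fraction of lifetime risk removed for covered
                               # workers; filled by calibration
  LEV: {}                 # same fields; effectiveness 0.93, coverage 0.40
  PPE: {}                 # same fields; effectiveness 0.90, coverage 1.00,
                          # protection factor fixed at 1 (one respirator per worker)

econ:
  qaly_value:             # CAD per quality-adjusted life-year (150000;
                          # sensitivity range 100000-200000)
  discount_rate:          # annual, fraction (0.03)
  payroll_loading:        # employer payroll add-on to earnings, fraction (0.14)
  participation_after_treatment:  # labour-force participation of survivors (0.77)
  survival_probability:   # lung-cancer survival probability (0.09)
  sex_split:              # {male: 0.7, female: 0.3}; must sum to 1
  age_probs:              # 13 probabilities over five-year bins 25-29 .. 85+,
                          # summing to 1; default unimodal with mode at 70-74
  home_production_value:  # CAD per year of lost home production (15000)
  quality_weight:         # QALYs lost per life-year lost for decedents (0.83)
  survivor_morbidity_qaly: # QALYs lost by survivors during treatment (1.0)
  direct_cost_cv:         # coefficient of variation of the Gaussian direct
                          # cost in Monte-Carlo mode (0.2)
  retirement_age:         # earnings-loss horizon, years (65)
  currency_year:          # label only (2017)

calibration:              # back-derived constants; omit the whole block to get
                          # identity defaults (risk_scale 1, zero reductions)
  risk_scale:             # multiplier on category lifetime risks
  per_case_cost:          # expected lifetime societal cost of one case, CAD
  cost_shares:            # {direct, indirect, intangible}; must sum to 1
  unit_costs:             # {WM, LEV, PPE}, CAD per unit
  risk_reduction:         # {WM, LEV, PPE}, fraction of risk removed in the
                          # covered slice
  qaly_at_calibration:    # QALY value at which the cost shares were anchored
  calibrated:             # boolean; when true the constants above are applied
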