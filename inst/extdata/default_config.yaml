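workers_total: 91000.0
risk_mode: calibrated_reduction
exposure:
- name: low
  lower: 0.0
  upper: 0.0125
  probability: 0.47
  lifetime_risk: 0.00091
- name: medium
  lower: 0.0125
  upper: 0.025
  probability: 0.39
  lifetime_risk: 0.0012
- name: high
  lower: 0.025
  probability: 0.14
  lifetime_risk: 0.0014
- name: negligible
  lower: 0.0
  upper: 0.0
  probability: 0.0
  lifetime_risk: 0.0
interventions:
  WM:
    name: WM
    reported_effectiveness: 0.82
    field_factor: 0.75
    coverage: 0.6
    protection_factor_mean: 5.0
    protection_factor_range:
    - 1.0
    - 10.0
    protection_factor_sd: 1.5
    calibrated_risk_reduction: 0.0
  LEV:
    name: LEV
    reported_effectiveness: 0.93
    field_factor: 0.75
    coverage: 0.4
    protection_factor_mean: 5.0
    protection_factor_range:
    - 1.0
    - 10.0
    protection_factor_sd: 1.5
    calibrated_risk_reduction: 0.0
  PPE:
    name: PPE
    reported_effectiveness: 0.9
    field_factor: 0.75
    coverage: 1.0
    protection_factor_mean: 1.0
    protection_factor_range:
    - 1.0
    - 1.0
    protection_factor_sd: 0.0
    calibrated_risk_reduction: 0.0
econ:
  qaly_value: 150000.0
  discount_rate: 0.03
  payroll_loading: 0.14
  participation_after_treatment: 0.77
  survival_probability: 0.09
  sex_split:
    male: 0.7
    female: 0.3
  age_probs:
  - 0.00026587605839
  - 0.001035904517807
  - 0.003439324119909
  - 0.009730594317916
  - 0.023459486984329
  - 0.048195949165274
  - 0.084375322829314
  - 0.125873190468226
  - 0.160016186430977
  - 0.173343465379342
  - 0.160016186430977
  - 0.125873190468226
  - 0.084375322829314
  home_production_value: 15000.0
  quality_weight: 0.83
  survivor_morbidity_qaly: 1.0
  direct_cost_cv: 0.2
  retirement_age: 65.0
  currency_year: 2017.0
calibration:
  risk_scale: 1.0
  per_case_cost: .na.real
  cost_shares:
    direct: .na.real
    indirect: .na.real
    intangible: .na.real
  unit_costs:
    WM: .na.real
    LEV: .na.real
    PPE: .na.real
  risk_reduction:
    WM: 0.0
    LEV: 0.0
    PPE: 0.0
  qaly_at_calibration: .na.real
  cost_model_scales:
    direct_per_case: .na.real
    scale_indirect: .na.real
    scale_intangible: .na.real
  calibrated: no
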