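# Published aggregate results used as calibration anchors.
# All money in 2017 Canadian dollars.
#
# baseline_cases / baseline_burden: expected lung-cancer cases and total
#   societal cost with no intervention.
# averted_cases / intervention_cost: the three single-intervention strategy
#   rows (cases averted; total implementation cost).
# cost_components: direct / indirect / intangible averted-cost components of
#   the all-intervention (WM-LEV-PPE) column, used only for their shares.
baseline_cases: 110
baseline_burden: 189000000
averted_cases:
  WM: 55
  LEV: 40
  PPE: 96
intervention_cost:
  WM: 42000000
  LEV: 15500000
  PPE: 81100000
cost_components:
  direct: 9500000
  indirect: 41200000
  intangible: 133900000
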