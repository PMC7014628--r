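Package: silicaCBA
Title: Probabilistic Cost-Benefit Analysis of Silica Exposure Reduction
    Interventions in Construction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic economic evaluation of occupational silica
    exposure reduction interventions (wet methods, local exhaust ventilation,
    personal protective equipment) for a construction-sector workforce.
    Implements a discrete influence diagram (chance, decision and utility
    nodes) with exact inference by enumeration and Monte-Carlo sampling,
    an incidence-based lifetime societal cost model for occupational lung
    cancer (direct, indirect and intangible components, discounted), a
    calibration procedure that back-derives unit costs, per-case costs and
    per-intervention risk reductions from published aggregate results, and
    net-benefit / benefit-cost comparison of seven intervention strategies
    with one-way sensitivity analysis. A synthetic worker-cohort generator
    provides a stochastic oracle for every enumerated expectation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
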