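Package: monitorCE
Title: Cost-Effectiveness Modelling of Automated Vital-Signs Monitoring on
    General Wards
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Decision-analytic cost-effectiveness and cost-utility modelling
    of an automated vital-signs monitoring and notification system compared
    with standard spot-check monitoring on general hospital wards. Provides
    a validated model-parameter bundle (event probabilities, principal-event
    distributions, lifetime costs and quality-adjusted life expectancies,
    device prices, resource use), device-cost annualization by straight-line
    depreciation or equivalent annual cost, a deterministic one-shot
    decision-tree engine with dominance, net monetary benefit and ICER
    outputs, probabilistic sensitivity analysis with cost-effectiveness
    acceptability curves, one-way sensitivity, threshold and subgroup
    analyses, a synthetic patient-level cohort generator, and regression
    machinery (negative-binomial event counts, gamma cost models,
    multinomial discharge states, non-parametric bootstrap) to recover model
    inputs from patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    nnet,
    yaml,
    jsonlite,
    stats,
    tools,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
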