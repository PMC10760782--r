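Package: tccmodel
Title: Markov Cohort Cost-Effectiveness Model for Toileting and Containment Care
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A cohort state-transition (Markov) model for the health-economic
    evaluation of toileting and containment care strategies for older adults
    with urinary or faecal incontinence. The cohort moves across care-need
    groups and care stages (degrees of toileting success) in two-month cycles
    over a lifetime horizon, with skin-health levels assigned per cycle as a
    memoryless mixture. The package accumulates discounted quality-adjusted
    life years, costs by category, care hours and product-disposal mass,
    compares two care strategies (incremental costs and effects, dominance,
    ICER), and quantifies parameter uncertainty through one-way (tornado)
    sensitivity analysis and probabilistic sensitivity analysis with
    Beta/Dirichlet/Gamma/Normal parameter distributions, including
    cost-effectiveness plane summaries and acceptability curves. Ships a
    Canadian nursing-home case study comparing sensor-based digital
    bladder-diary care planning with conventional continence care, a synthetic
    parameter generator for testing, CSV/JSON result export and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    rlang,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
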