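Package: ceamarkov
Title: Markov Cohort Cost-Effectiveness Analysis for Disease-Modifying
    Therapies
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Discrete-time Markov cohort modelling for cost-effectiveness
    analysis of disease-modifying therapies against standard of care,
    built around a four-state (mild/moderate/severe/death) Alzheimer's
    disease scenario. Provides validated row-stochastic transition
    matrices, relative-risk treatment-effect adjustments, discounted cost
    and QALY accrual, incremental cost-effectiveness ratios and net
    monetary benefit, one-way deterministic sensitivity analysis with
    tornado ordering, probabilistic sensitivity analysis with
    method-of-moments beta/gamma parameter distributions,
    cost-effectiveness acceptability curves, a random-scenario generator
    with an individual-level microsimulation oracle, and a config-driven
    reporting pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
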