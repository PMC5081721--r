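Package: tfacea
Title: Cost-Effectiveness Analysis of EU-Level Trans-Fat Reduction Policies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A sex- and age-stratified four-state Markov cohort model for the
    economic evaluation of European-Union-level policy options that reduce
    population intake of industrially produced trans fatty acids. The package
    generates synthetic EU-like demographic and epidemiologic inputs, builds
    intake phase-out trajectories for four policy options, converts intake into
    time-varying coronary-artery-disease transition probabilities, runs a closed
    cohort over a lifetime horizon, and reports discounted costs, disability-
    adjusted life years, incremental cost-effectiveness ratios with dominance
    classification, and a probabilistic sensitivity analysis with
    cost-effectiveness-plane export.
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
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
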