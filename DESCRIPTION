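Package: equicea
Title: Equity-Aware Markov Cost-Utility Modelling of Cancer Interventions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-state Markov cohort model (alive with cancer, death from
    cancer, death from other causes) for cost-utility analysis of cancer
    treatment interventions, with explicit layering of ethnic heterogeneity
    in input parameters. Implements monthly-cycle cohort simulation from
    diagnosis to age 110, retrospective disease-phase trajectories valued in
    health-adjusted life years (HALYs) with disability weights and a
    background-morbidity envelope, discounted health-system costing,
    incremental cost-effectiveness ratios, per-100,000-population gains, and
    a five-model scenario ladder that switches cancer survival, disability
    weights, background mortality, and prevalent comorbidity between
    reference-group and group-specific values. Ships a seeded generator of
    synthetic New Zealand-like parameter bundles stratified by ethnicity,
    sex, age band, and small-area deprivation so the full pipeline runs
    without access to restricted registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
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
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
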