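Package: swgeepower
Title: Fast GEE Power and Small-Sample Analysis for Stepped Wedge Cluster
    Randomized Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analytic (non-simulation) power calculation for generalized
    estimating equations (GEE) analysis of complete and incomplete stepped
    wedge cluster randomized trials, together with the estimation machinery
    the power method predicts for: GEE with matrix-adjusted estimating
    equations (MAEE) for intracluster correlations, bias-corrected sandwich
    variance estimators (Kauermann-Carroll, Mancl-DeRouen, Fay-Graubard),
    and correlated-data simulators (conditional linear family for binary
    outcomes, multivariate normal for continuous outcomes) used to verify
    predicted power against empirical size and power. Supports incomplete
    designs with implementation periods and staggered cluster entry or
    termination via design-pattern/completeness-matrix algebra, five
    intracluster correlation structures, and average or incremental
    intervention-effect marginal models.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
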