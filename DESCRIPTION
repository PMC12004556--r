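Package: tsasens
Title: Trial Sequential Analysis and Its Sensitivity to Between-Study
    Variance Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for trial sequential analysis (TSA) of binary-outcome
    random-effects meta-analyses: inverse-variance pooling of log odds
    ratios from 2x2 tables, six between-study variance (tau-squared)
    estimators (DerSimonian-Laird, REML, ML, Paule-Mandel, Sidik-Jonkman,
    Hunter-Schmidt), diversity (D2) and the diversity-based adjustment
    factor, the diversity-adjusted required information size, Lan-DeMets
    O'Brien-Fleming-type alpha-spending boundaries by recursive numerical
    integration, cumulative z-curve monitoring, and a sensitivity sweep
    that re-runs the full TSA under each estimator and summarizes
    disagreement with ranges and quartile coefficients of variation.
    Includes a seeded generator of synthetic binomial meta-analysis data
    and Monte-Carlo error-rate simulations contrasting sequential
    monitoring with naive repeated significance testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr
Config/testthat/edition: 3
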