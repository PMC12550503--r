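Package: sepsiswatch
Title: Early Warning of Pediatric Sepsis from Irregular EHR Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for hour-level early warning of pediatric sepsis from
    irregularly sampled electronic health record time series. Inter-measurement
    interval histograms set a per-variable interpolation window (70 percent
    quantile) and successive-window correlations set how many historical
    windows may be referenced; a multivariate Gaussian process then imputes
    retained variables onto a regular hourly grid and is merged with a
    correlation-weighted windowed estimate. A bank of thirteen horizon-specific
    models (gated recurrent unit encoder feeding a gradient-boosted classifier)
    scores sepsis risk 0-12 hours ahead; evaluation covers AUROC, AUPRC,
    sensitivity, specificity, Brier score and Youden index with bootstrap
    confidence intervals and Shapley attributions; a tiered alert simulator
    replays episodes and reports lead times and agreement statistics. A seeded
    synthetic-cohort generator emulates the statistical structure of a
    two-class pediatric cohort for testing and demonstration.
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
    purrr,
    rlang,
    readr,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
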