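Package: droughtlegacy
Title: Drought Impact and Legacy-Effect Detection in Ecosystem Flux and Sap-Flow Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify direct drought impacts and to detect (or rule
    out) post-drought legacy effects in daily ecosystem time series. Provides
    a sensor-degradation-aware processing pipeline for long-term thermal
    dissipation sap-flow records (daytime aggregation, availability filtering,
    seasonal-trend removal, moving-window variance normalization, per-tree
    averaging), segment-wise normalization of eddy-covariance fluxes across
    instrument changes, a random-forest residual framework with leave-one-out
    uncertainty bands that tests post-drought residuals against the model's
    own null envelope, SD-scaled drought-impact statistics and record-extreme
    run detection, and a seeded synthetic-scenario generator (seasonal
    drivers, bucket soil moisture, nonlinear flux responses, degrading
    multi-sensor sap flow, optional injected legacy suppression) so the whole
    pipeline is testable end to end without site data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    randomForest,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml,
    zoo
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
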