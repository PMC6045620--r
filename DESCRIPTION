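Package: firecast
Title: Seasonal Burned-Area Forecasting from Standardized Precipitation Indices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An empirical climate-fire modelling and forecasting pipeline for
    seasonal burned area on regular latitude-longitude grids. Computes
    nonparametric (rank-based) standardized precipitation and water-balance
    indices (SPI, SPEI with Thornthwaite potential evapotranspiration) and a
    standardized temperature indicator; fits per-cell linear burned-area
    models on standardized drought indices by robust (bisquare IRLS)
    regression under leave-one-out cross-validation, searching accumulation
    windows of 3, 6 and 12 months and lags of 0 to 5 months; bias-corrects
    seasonal forecast archives by leave-one-out linear scaling and merges
    observations with forecasts across the issue date to drive the fitted
    models; and verifies forecasts with correlation, significant-area,
    mean-error and climatology null-model diagnostics. Includes a synthetic
    gridded-data generator with known ground truth for end-to-end testing
    and parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite
Config/testthat/edition: 3
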