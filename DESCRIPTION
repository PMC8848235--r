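Package: bloodbankr
Title: Platelet Demand Forecasting and Blood Bank Inventory Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forecasts daily platelet demand from clinical time-series
    covariates and drives a shelf-life-aware blood bank inventory
    simulator with an explicit ordering policy. Implements a LASSO and a
    long short-term memory (LSTM) network under rolling-origin
    recalibration with blocked cross-validation, forecast-accuracy
    metrics (RMSE, r-squared, MAPE) with bootstrap confidence intervals
    and CI-derived p-values, a FIFO perishable-inventory model with
    emergency purchases, and exhaustive grid search over the inventory
    policy parameters by total cost. A calibrated synthetic-data
    generator emulates hospital transfusion demand so the full pipeline
    is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
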