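Package: tdcal
Title: Time-Dependent Crop Model Parameter Calibration with Parallel
    Bayesian Optimization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Calibrates time-dependent cultivar parameters of a crop
    simulation model from county yield time series. Training years are
    divided into overlapping main and auxiliary time-windows; each
    window's parameters are estimated by parallel Bayesian optimization
    (several Gaussian-process surrogate instances with heterogeneous
    kernels and acquisition functions that pool all objective
    evaluations); per-year parameter values are formed as
    length-weighted averages over the windows covering each year; and an
    autoregressive trend model with PACF order selection and an
    augmented Dickey-Fuller diagnostic forecasts next-year parameters.
    Includes a synthetic crop-yield simulator with known ground truth
    for parameter-recovery experiments, evaluation metrics (RMSE, RRMSE,
    R squared), and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lhs,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
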