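Package: segits
Title: Segmented Regression for Interrupted Time Series Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits segmented (piecewise linear) regression models to single-series
    interrupted time series data under the two common parametrizations of the
    intervention interaction term (time, and time since intervention), using
    closed-form ordinary least squares estimators with full covariance-based
    inference. Distinguishes the immediate effect (change in levels at
    intervention onset) from the difference in intercepts, translates fitted
    models between the two parametrizations, and provides a Monte Carlo
    simulation harness for parameter recovery and standard-error calibration,
    CSV input/output, publication-style fitted-model plots, and a command-line
    interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
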