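Package: rarecast
Title: Forecasting Annual Counts of Rare Events with Change-Point,
    ARIMA, and Hybrid ARIMA-ANN Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for modelling and forecasting annual counts of rare
    events from event-time and annual-count data.  Implements a Bayesian
    change-point non-homogeneous Poisson process with a Weibull-geometric
    intensity (adaptive Metropolis sampling, posterior predictive annual
    forecasts), AIC-based ARIMA order selection with Augmented
    Dickey-Fuller differencing, and a hybrid ARIMA-ANN in which a single
    hidden layer neural network models the nonlinear structure of ARIMA
    residuals, with sequential network construction driven by an algebraic
    prediction-risk estimate.  Includes the 1966-2020 U.S. mass-shooting
    series from the Violence Project as an embedded fixture, seeded
    synthetic-data generators for both data representations, and a
    rolling-origin evaluation harness (RMSE/MAPE, prediction-interval
    comparison).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
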