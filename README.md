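# rarecast

Forecasting annual counts of rare events — with the U.S. mass-shooting
record (Violence Project, 1966–2020) embedded as the worked dataset — by
three models with very different views of the same history:

1. **A Bayesian change-point model**: event *days* follow a
   non-homogeneous Poisson process whose Weibull-geometric intensity
   λ(t) = (α/β)(t/β)^(α−1) / (1 − ρ e^(−(t/β)^α)) may switch parameters
   at unknown change points. Uniform priors, adaptive tempered Metropolis
   sampling (compiled), posterior-predictive annual forecasts with
   credible intervals.
2. **ARIMA(p,d,q) with drift**: annual counts fitted by maximum
   likelihood, the differencing order picked by an Augmented
   Dickey–Fuller procedure, (p,q) picked by the RSS-based AIC
   approximation AIC = n[log(2π·RSS/n)+1] + 2(p+q) over a stepwise (or
   exhaustive) search, Gaussian prediction intervals.
3. **Hybrid ARIMA–ANN**: y_t = L_t + N_t, where the ARIMA fit supplies
   the linear part and a single-hidden-layer network (Tanh hidden,
   Sigmoid output) learns the nonlinear structure of the ARIMA residuals
   from their n most recent lags. Architecture is chosen by sequential
   network construction minimising the prediction-risk estimate
   P̂ = J(1 + 2Q/I), Q = n·m + m.

A rolling-origin harness (training windows 1966–T, T = 2003…2014)
compares all variants by train/test RMSE and MAPE, and a future-forecast
module contrasts five-year forecasts with and without the most recent
year. Seeded synthetic-data generators (piecewise-NHPP event streams,
annual series with a known ARIMA(0,1,1) core plus a known nonlinear
residual signal) make every stage testable offline.

## Worked example

```r
library(rarecast)
counts <- mass_shooting_counts()        # annual counts 1966-2019

sel <- arima_order_search(counts)       # ADF picks d, AIC picks (p,q)
sel$order
#> p d q
#> 0 1 1

forecast_arima(sel$fit, h = 1, level = 0.95)
#>   h    point    lower    upper       se
#> 1 1 6.000001 3.334339 8.665664 1.360057
```

The selected order is (0,1,1) — it is (0,1,1) for *every* training window
1966–T, T = 2003…2014 — and the one-step 95% prediction interval for the
2020 count is [3.33, 8.67] around a point forecast of 6.0 events.

```r
hyb <- fit_hybrid(counts, n_max = 5, seed = 1)
hyb
#> <rc_hybrid> ARIMA(0,1,1) + drift + ANN(n = 1, m = 0, Q = 0), J = 0.03385

forecast_hybrid(hyb, h = 1)
#>   h    point    lower    upper   linear  nonlinear
#> 1 1 5.871679 3.206016 8.537342 6.000001 -0.1283226
```

On these data the risk criterion selects a minimal network (here the
constant model, Q = 0): the ARIMA residuals carry almost no
lag-predictable structure, and the hybrid adjustment is a small downward
shift (−0.13) of the linear forecast. The change-point model is fitted
with `sample_posterior()` on `mass_shooting_events()` and forecast with
`forecast_annual()`; at the default budget (4 chains × 150,000
iterations, ~5 minutes) it yields a 95% posterior-predictive interval of
about [0, 13] events for 2020.

A thin command-line front end over the same functions is installed at
`inst/cli/rarecast.R` (subcommands `simulate`, `fit-changepoint`,
`fit-arima`, `fit-hybrid`, `evaluate`, `forecast-future`).

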