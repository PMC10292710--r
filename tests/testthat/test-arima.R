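test_that("ADF-based differencing picks the smallest stationarising order", {
  ac <- mass_shooting_counts()
  # two representative training windows; the full sweep runs in the
  # acceptance suite
  for (T_last in c(2003, 2014)) {
    tr <- split_by_year(ac, T_last)$train
    expect_identical(adf_select_d(tr$counts), 1L)
  }
  # long white noise: the domain floor d = 1
  set.seed(3)
  expect_identical(adf_select_d(rnorm(200)), 1L)
  # quadratic trend needs a second difference
  set.seed(4)
  expect_identical(adf_select_d((1:50)^2 * 0.1 + rnorm(50, 0, 0.5)), 2L)
  expect_error(adf_select_d(rnorm(5)), "short")
})

test_that("maximum-likelihood fitting recovers a known MA coefficient", {
  y <- simulate_hybrid_series(hybrid_scenario(5000, theta1 = 0.5,
                                              drift = 0.02, noise_sd = 1,
                                              seed = 2))
  fit <- fit_arima(y, c(0, 1, 1))
  # R parameterises the MA polynomial with the opposite sign
  expect_equal(unname(-fit$coef["ma1"]), 0.5, tolerance = 0.05)
  expect_length(fit$residuals, 5000)
  expect_equal(fit$rss, sum(fit$residuals^2))
  expect_equal(fit$fitted + fit$residuals, y$counts)
})

test_that("degenerate and undersized inputs are handled", {
  const <- annual_counts(rep(3, 20), 1990)
  fit <- fit_arima(const, c(0, 1, 0), include_drift = FALSE)
  # the first residual carries a tiny initialisation transient
  expect_lt(max(abs(fit$residuals)), 0.01)
  expect_equal(fit$residuals[-1], rep(0, 19), tolerance = 1e-8)
  expect_error(fit_arima(annual_counts(c(1, 2, 3), 1990), c(2, 1, 2)),
               "too short")
})

test_that("the RSS-based AIC follows its defining arithmetic", {
  # RSS/n = 1/(2 pi) makes the log term vanish: AIC = n + 2(p+q)
  expect_equal(aic_rss(40 / (2 * pi), 40, 1, 1), 44)
  # doubling RSS adds n log 2
  expect_equal(aic_rss(4, 50, 0, 1) - aic_rss(2, 50, 0, 1), 50 * log(2))
  # direct evaluation
  expect_equal(aic_rss(2, 50, 0, 1),
               50 * (log(2 * pi * 2 / 50) + 1) + 2)
  expect_error(aic_rss(0, 10, 0, 0), "RSS")
})

test_that("order search scores candidates exhaustively or stepwise", {
  ac <- mass_shooting_counts()
  tr <- split_by_year(ac, 2006)$train
  ex <- arima_order_search(tr, stepwise = FALSE)
  expect_identical(ex$n_candidates, 36L)
  # the winner minimises the RSS-based AIC over all scored candidates
  expect_true(all(ex$fit$aic_rss <= ex$aic_table$aic + 1e-12))

  st <- arima_order_search(tr, stepwise = TRUE)
  expect_identical(unname(st$order), c(0L, 1L, 1L))
  expect_identical(unname(st$order["d"]), 1L)

  # stepwise recovers the true order of a synthetic integrated MA(1)
  ys <- simulate_hybrid_series(hybrid_scenario(800, theta1 = 0.5,
                                               drift = 0.05, noise_sd = 1,
                                               seed = 9))
  expect_identical(unname(arima_order_search(ys)$order), c(0L, 1L, 1L))
})

test_that("forecast intervals are Gaussian, symmetric and widen with horizon", {
  fit <- fit_arima(mass_shooting_counts(), c(0, 1, 1))
  fc <- forecast_arima(fit, h = 5, level = 0.95)
  expect_equal(fc$point - fc$lower, fc$upper - fc$point, tolerance = 1e-10)
  expect_true(all(diff(fc$upper - fc$lower) > 0))
  fc99 <- forecast_arima(fit, h = 1, level = 0.99)
  expect_gt(fc99$upper - fc99$lower, fc$upper[1] - fc$lower[1])
  # width scales exactly with the normal quantile
  expect_equal((fc99$upper - fc99$lower) / (fc$upper[1] - fc$lower[1]),
               stats::qnorm(0.995) / stats::qnorm(0.975), tolerance = 1e-10)
})

test_that("the one-step (0,1,1) forecast is an exponentially weighted average", {
  ac <- mass_shooting_counts()
  fit <- fit_arima(ac, c(0, 1, 1), include_drift = FALSE)
  alpha_ses <- 1 + unname(fit$coef["ma1"])
  level <- ac$counts[1]
  for (t in 2:length(ac$counts)) {
    level <- alpha_ses * ac$counts[t] + (1 - alpha_ses) * level
  }
  expect_equal(forecast_arima(fit, 1)$point, level, tolerance = 1e-6)
})
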