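test_that("residual extraction reproduces one-step in-sample errors", {
  const <- annual_counts(rep(4, 20), 1990)
  fit <- fit_arima(const, c(0, 1, 0), include_drift = FALSE)
  # all zero apart from a tiny initialisation transient on the first value
  expect_lt(max(abs(extract_residuals(const, fit))), 0.01)

  ac <- mass_shooting_counts()
  f <- fit_arima(ac, c(0, 1, 1))
  e <- extract_residuals(ac, f)
  expect_equal(mean(e), mean(ac$counts - f$fitted))
  expect_error(extract_residuals(annual_counts(1:5, 1990), f), "misaligned")
})

test_that("ARIMA residuals retain an injected nonlinear signal", {
  # even-function (quadratic) signal survives the linear pre-whitening
  scq <- hybrid_scenario(200, theta1 = 0.5, drift = 0.05,
                         nonlinear_fn = "quadratic", noise_sd = 1, seed = 7)
  yq <- simulate_hybrid_series(scq)
  set.seed(7)
  eps <- rnorm(202, 0, 1)
  injected <- 0.5 * eps[(1:200) + 1]^2
  e <- extract_residuals(yq, fit_arima(yq, c(0, 1, 1)))
  expect_gt(stats::cor(e, injected), 0.3)
})

test_that("sequential network construction finds genuine lag structure", {
  # residuals with known 2-lag dependence: the selected input count must
  # reach back at least two lags (checked over seeds)
  hits <- 0
  for (sd in 1:3) {
    e <- gen_two_lag_residuals(250, 40 + sd)
    en <- normalize_residuals(e)$values
    s <- snc_select(en, n_max = 5, restarts = 2, max_iterations = 3000,
                    lambda = 0.001, seed = sd)
    expect_identical(nrow(s$step1), 11L)          # m = 0..10
    expect_lte(nrow(s$step2), 5L)                 # n = 1..n_max
    expect_true(all(s$step1$risk >= s$step1$J))
    hits <- hits + (s$n_inputs >= 2)
  }
  expect_gte(hits, 2)

  # white-noise residuals under a strong penalty: a minimal network
  small <- vapply(1:3, function(sd) {
    set.seed(200 + sd)
    s <- snc_select(normalize_residuals(rnorm(150))$values, n_max = 5,
                    restarts = 2, max_iterations = 1500, lambda = 0.05,
                    seed = sd)
    ann_architecture(s$n_inputs, s$m_hidden)$Q
  }, integer(1))
  expect_true(all(small <= 10))
})

test_that("hybrid forecasts compose the linear and nonlinear parts", {
  ac <- mass_shooting_counts()
  fit <- fit_hybrid(ac, arch = ann_architecture(3, 2), restarts = 2,
                    max_iterations = 1500, seed = 5)

  # manual composition at h = 1
  fa <- forecast_arima(fit$arima, 1)
  x <- rev(utils::tail(fit$residuals_norm, fit$n_lags))
  nhat <- denormalize_residuals(ann_forward(fit$weights, x), fit$norm_spec)
  fh <- forecast_hybrid(fit, 1)
  expect_equal(fh$point, fa$point + nhat, tolerance = 1e-12)
  expect_equal(fh$nonlinear, nhat, tolerance = 1e-12)

  # multi-step recursion equals manual chaining with appended predictions
  fh3 <- forecast_hybrid(fit, 3)
  hist <- fit$residuals_norm
  manual <- numeric(3)
  fa3 <- forecast_arima(fit$arima, 3)
  for (j in 1:3) {
    v <- ann_forward(fit$weights, rev(utils::tail(hist, fit$n_lags)))
    hist <- c(hist, v)
    manual[j] <- fa3$point[j] + denormalize_residuals(v, fit$norm_spec)
  }
  expect_equal(fh3$point, manual, tolerance = 1e-12)
})

test_that("a zero nonlinear adjustment leaves the ARIMA forecast untouched", {
  ac <- mass_shooting_counts()
  fit <- fit_hybrid(ac, arch = ann_architecture(1, 0), restarts = 1,
                    max_iterations = 50, seed = 1)
  # force the constant network output to denormalise exactly to zero
  target <- (0 - fit$norm_spec$min_value) /
    (fit$norm_spec$max_value - fit$norm_spec$min_value)
  fit$weights$b2 <- stats::qlogis(target)
  fa <- forecast_arima(fit$arima, 2)
  fh <- forecast_hybrid(fit, 2)
  expect_equal(fh$point, fa$point, tolerance = 1e-12)
  expect_equal(fh$lower, fa$lower, tolerance = 1e-12)
  expect_equal(fh$upper, fa$upper, tolerance = 1e-12)
})

test_that("interval policies shift or resample as configured", {
  iv <- data.frame(lower = c(1, 2), upper = c(5, 6))
  shifted <- hybrid_prediction_interval(iv, c(0.5, -1))
  expect_equal(shifted$lower, c(1.5, 1))
  expect_equal(shifted$upper, c(5.5, 5))

  ac <- mass_shooting_counts()
  fit <- fit_hybrid(ac, arch = ann_architecture(2, 1), restarts = 1,
                    max_iterations = 500, seed = 2)
  b1 <- forecast_hybrid(fit, 2, interval_policy = "bootstrap", seed = 77)
  b2 <- forecast_hybrid(fit, 2, interval_policy = "bootstrap", seed = 77)
  expect_identical(b1, b2)
  expect_true(all(b1$lower <= b1$point & b1$point <= b1$upper))
})
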