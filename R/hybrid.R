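## Hybrid ARIMA-ANN: the ARIMA fit estimates the linear component L_t of the
## series, a single-hidden-layer network models the nonlinear structure of
## the ARIMA residuals from their n most recent lags, and the hybrid
## forecast is y_hat = L_hat + N_hat with recursive residual propagation for
## multi-step horizons.  The network architecture (m hidden nodes, then n
## input lags) is chosen by sequential network construction (SNC) minimising
## the algebraic prediction risk.

#' One-step in-sample residuals of an ARIMA fit
#'
#' `e_t = y_t - L_hat_t` where `L_hat_t` are the fit's one-step in-sample
#' predictions.
#'
#' @param x the series the fit was produced on ([annual_counts] or numeric).
#' @param fit an `rc_arima` from [fit_arima].
#' @return numeric residual vector, one per observation.
#' @export
extract_residuals <- function(x, fit) {
  y <- if (inherits(x, "annual_counts")) x$counts else as.numeric(x)
  stopifnot(inherits(fit, "rc_arima"))
  if (length(y) != fit$n) stop("extract_residuals: misaligned lengths")
  y - fit$fitted
}

#' Min-max normalisation of residuals to [0, 1]
#'
#' The normalisation range is learned from training residuals only; values
#' outside the range at prediction time are clipped to `[0, 1]` with a
#' warning.
#'
#' @param e residuals to normalise.
#' @param spec optional existing spec (list with `min_value`, `max_value`);
#'   if `NULL` a new spec is fitted from `e`.
#' @return list with `values` in `[0, 1]` and the `spec`.
#' @export
normalize_residuals <- function(e, spec = NULL) {
  if (is.null(spec)) {
    spec <- list(min_value = min(e), max_value = max(e))
    if (spec$max_value <= spec$min_value) {
      stop("constant_residuals: max must exceed min to fit a normalisation")
    }
  }
  v <- (e - spec$min_value) / (spec$max_value - spec$min_value)
  if (any(v < 0 | v > 1)) {
    warning("normalize_residuals: values outside the training range clipped")
    v <- pmin(pmax(v, 0), 1)
  }
  list(values = v, spec = spec)
}

#' Invert the min-max normalisation
#'
#' @param v normalised values.
#' @param spec normalisation spec.
#' @return values on the residual scale.
#' @export
denormalize_residuals <- function(v, spec) {
  v * (spec$max_value - spec$min_value) + spec$min_value
}

#' Lagged-residual supervised design matrix
#'
#' Row `i` maps the `n` most recent residuals before time `t` (columns in
#' order `e_{t-1}, e_{t-2}, ..., e_{t-n}`) to the target `e_t`, giving
#' `I = length(e) - n` rows.
#'
#' @param e (normalised) residual series.
#' @param n number of lags, `< length(e)`.
#' @return list with `X` (I x n), `y` (length I), `I`.
#' @export
build_lag_matrix <- function(e, n) {
  N <- length(e)
  if (N <= n) stop("build_lag_matrix: need more residuals than lags")
  I <- as.integer(N - n)
  X <- vapply(seq_len(n), function(j) e[(n - j + 1):(N - j)],
              numeric(I))
  X <- matrix(X, nrow = I)
  list(X = X, y = e[(n + 1):N], I = I)
}

#' Sequential network construction
#'
#' Two-step architecture search minimising the prediction risk
#' `P_hat = J * (1 + 2 Q / I)` with every candidate trained on all available
#' data.  Step 1 fixes `n = n_max` and varies the hidden nodes
#' `m = 0..m_max`; step 2 fixes the chosen `m` and varies the input lags
#' `n = 1..n_max`.  Each candidate is trained `restarts` times from
#' different seeded initialisations and the median risk is used, because
#' single-run selection is dominated by initialisation noise.  Ties break
#' toward the smaller architecture.
#'
#' @param e_norm normalised residual series.
#' @param n_max maximum number of input lags (3, 5, 7 or 10 in the study
#'   design, but any positive value is accepted).
#' @param m_max maximum hidden nodes (default 10).
#' @param lambda,max_iterations,learning_rate,tol passed to [train_ann].
#' @param restarts seeded restarts per candidate (default 5; 1 mimics
#'   single-run selection).
#' @param seed base seed; candidate seeds are derived deterministically.
#' @return list with `n_inputs`, `m_hidden`, and the step-1/step-2 candidate
#'   tables (`m` or `n`, median `J`, `Q`, `I`, `risk`).
#' @export
snc_select <- function(e_norm, n_max, m_max = 10L, lambda = 0.01,
                       max_iterations = 5000L, learning_rate = 0.2,
                       tol = 1e-9, restarts = 5L, seed = 1L) {
  if (length(e_norm) <= n_max) {
    stop("snc_select: not enough residuals for n_max lags")
  }
  eval_cand <- function(n, m, tag) {
    lm_ <- build_lag_matrix(e_norm, n)
    arch <- ann_architecture(n, m)
    Js <- vapply(seq_len(restarts), function(r) {
      w <- train_ann(lm_$X, lm_$y, arch, lambda = lambda,
                     max_iterations = max_iterations,
                     learning_rate = learning_rate, tol = tol,
                     seed = seed + 1009L * tag + r)
      w$J
    }, numeric(1))
    J <- stats::median(Js)
    data.frame(n = n, m = m, J = J, Q = arch$Q, I = lm_$I,
               risk = prediction_risk(J, arch$Q, lm_$I))
  }
  step1 <- do.call(rbind, lapply(0:m_max, function(m) {
    eval_cand(n_max, m, tag = m)
  }))
  m_sel <- step1$m[which.min(step1$risk)]
  step2 <- do.call(rbind, lapply(seq_len(n_max), function(n) {
    eval_cand(n, m_sel, tag = 100L + n)
  }))
  n_sel <- step2$n[which.min(step2$risk)]
  list(n_inputs = n_sel, m_hidden = m_sel, step1 = step1, step2 = step2)
}

#' Fit the hybrid ARIMA-ANN model
#'
#' Fits the ARIMA linear component, extracts and normalises its one-step
#' residuals, selects the network architecture by [snc_select] (unless
#' `arch` is given), and trains the final network (best of `restarts` seeded
#' runs by regularised cost).  In-sample hybrid fitted values are
#' `L_hat_t + N_hat_t` for the years where `n` lags exist and `L_hat_t`
#' before that.
#'
#' @param x training series ([annual_counts] or numeric).
#' @param n_max maximum input lags for the SNC search.
#' @param order ARIMA order (default `c(0, 1, 1)`).
#' @param include_drift include the ARIMA drift regressor (default `TRUE`).
#' @param arch optional fixed [ann_architecture] (skips SNC).
#' @param lambda,max_iterations,learning_rate,tol,restarts,seed training and
#'   selection controls, as in [snc_select].
#' @param m_max maximum hidden nodes for SNC.
#' @return object of class `rc_hybrid`.
#' @export
fit_hybrid <- function(x, n_max = 5L, order = c(0, 1, 1),
                       include_drift = TRUE, arch = NULL, lambda = 0.01,
                       max_iterations = 5000L, learning_rate = 0.2,
                       tol = 1e-9, restarts = 5L, m_max = 10L, seed = 1L) {
  af <- fit_arima(x, order, include_drift)
  e <- extract_residuals(x, af)
  nm <- normalize_residuals(e)
  snc <- NULL
  if (is.null(arch)) {
    snc <- snc_select(nm$values, n_max = n_max, m_max = m_max,
                      lambda = lambda, max_iterations = max_iterations,
                      learning_rate = learning_rate, tol = tol,
                      restarts = restarts, seed = seed)
    arch <- ann_architecture(snc$n_inputs, snc$m_hidden)
  }
  n <- if (arch$m_hidden == 0) max(arch$n_inputs, 1) else arch$n_inputs
  lm_ <- build_lag_matrix(nm$values, n)
  fits <- lapply(seq_len(restarts), function(r) {
    train_ann(lm_$X, lm_$y, arch, lambda = lambda,
              max_iterations = max_iterations,
              learning_rate = learning_rate, tol = tol,
              seed = seed + 7919L * r)
  })
  w <- fits[[which.min(vapply(fits, `[[`, numeric(1), "J_reg"))]]
  nhat_norm <- ann_forward(w, lm_$X)
  fitted <- af$fitted
  idx <- (n + 1):length(e)
  fitted[idx] <- fitted[idx] + denormalize_residuals(nhat_norm, nm$spec)
  structure(list(arima = af, weights = w, arch = arch, norm_spec = nm$spec,
                 residuals = e, residuals_norm = nm$values,
                 n_lags = n, snc = snc, fitted = fitted,
                 series = af$series, start_year = af$start_year,
                 lambda = lambda, seed = seed),
            class = "rc_hybrid")
}

#' @export
print.rc_hybrid <- function(x, ...) {
  cat(sprintf(
    "<rc_hybrid> ARIMA(%d,%d,%d)%s + ANN(n = %d, m = %d, Q = %d), J = %.4g\n",
    x$arima$order[1], x$arima$order[2], x$arima$order[3],
    if (x$arima$include_drift) " + drift" else "",
    x$arch$n_inputs, x$arch$m_hidden, x$arch$Q, x$weights$J))
  invisible(x)
}

#' Shift a prediction interval by a point adjustment
#'
#' Default interval policy for the hybrid model: the ARIMA interval is
#' shifted by the ANN point adjustment, preserving its width.
#'
#' @param interval data.frame with `lower` and `upper` columns.
#' @param adjustment per-row point adjustment.
#' @return the interval data.frame with both bounds shifted.
#' @export
hybrid_prediction_interval <- function(interval, adjustment) {
  interval$lower <- interval$lower + adjustment
  interval$upper <- interval$upper + adjustment
  interval
}

#' Forecast from the hybrid model
#'
#' `y_hat_{t+j} = L_hat_{t+j} + N_hat_{t+j}`: the ARIMA forecast plus the
#' denormalised network output.  Multi-step forecasts are recursive —
#' each predicted (normalised) residual is appended to the lag window before
#' the next step.  Intervals follow the chosen policy: `"shift"` moves the
#' ARIMA interval by the ANN adjustment; `"bootstrap"` resamples the
#' in-sample hybrid errors (seed-controlled) around the hybrid point
#' forecast.
#'
#' @param fit an `rc_hybrid`.
#' @param h forecast horizon.
#' @param level interval level (default 0.95).
#' @param interval_policy `"shift"` (default) or `"bootstrap"`.
#' @param n_boot bootstrap resamples (default 10000).
#' @param seed seed for the bootstrap policy.
#' @return data.frame with `h`, `point`, `lower`, `upper`, `linear`,
#'   `nonlinear`.
#' @export
forecast_hybrid <- function(fit, h = 1L, level = 0.95,
                            interval_policy = c("shift", "bootstrap"),
                            n_boot = 10000L, seed = 1L) {
  stopifnot(inherits(fit, "rc_hybrid"))
  interval_policy <- match.arg(interval_policy)
  fa <- forecast_arima(fit$arima, h = h, level = level)
  hist <- fit$residuals_norm
  n <- fit$n_lags
  if (length(hist) < n) stop("forecast_hybrid: insufficient residual history")
  nl <- numeric(h)
  for (j in seq_len(h)) {
    x <- rev(utils::tail(hist, n))
    v <- ann_forward(fit$weights, matrix(x, nrow = 1))
    hist <- c(hist, v)
    nl[j] <- denormalize_residuals(v, fit$norm_spec)
  }
  point <- fa$point + nl
  if (interval_policy == "shift") {
    iv <- hybrid_prediction_interval(fa[, c("lower", "upper")], nl)
  } else {
    set.seed(seed)
    err <- fit$series - fit$fitted
    a <- (1 - level) / 2
    iv <- t(vapply(seq_len(h), function(j) {
      bs <- point[j] + sample(err, n_boot, replace = TRUE)
      stats::quantile(bs, c(a, 1 - a), names = FALSE)
    }, numeric(2)))
    iv <- data.frame(lower = iv[, 1], upper = iv[, 2])
  }
  data.frame(h = seq_len(h), point = point, lower = iv$lower,
             upper = iv$upper, linear = fa$point, nonlinear = nl)
}
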