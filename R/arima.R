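## ARIMA(p,d,q) fitting (maximum likelihood via stats::arima, with a drift
## term), RSS-based AIC order scoring, ADF-based differencing selection, and
## Gaussian h-step prediction intervals.
##
## The drift term matters: the model actually fitted is ARIMA(p,d,q) on y_t
## with an external linear-trend regressor, which is what reproduces the
## reference auto-order tooling's `with_intercept` default.

#' Augmented Dickey-Fuller stationarity test (constant case)
#'
#' Regression `dy_t = c + g * y_{t-1} + sum_i d_i * dy_{t-i} + e_t` with the
#' augmentation lag chosen by AIC over `0..max_lag` (as in the common
#' auto-lag default).  The t-statistic of `g` is compared against the
#' MacKinnon (2010) finite-sample 5% response-surface critical value for the
#' constant case.
#'
#' @param x numeric series.
#' @param max_lag maximum augmentation lag; default
#'   `floor(12 * (n/100)^0.25)` capped to keep the regression estimable.
#' @param alpha significance level; only 0.05 critical values are tabulated.
#' @return list with `statistic`, `critical_value`, and `stationary`
#'   (`TRUE` when the unit root is rejected).
#' @export
adf_test <- function(x, max_lag = NULL, alpha = 0.05) {
  n <- length(x)
  if (n < 10) stop("adf_test: series too short")
  if (alpha != 0.05) stop("adf_test: only alpha = 0.05 is tabulated")
  dx <- diff(x)
  if (is.null(max_lag)) max_lag <- floor(12 * (n / 100)^0.25)
  max_lag <- max(0, min(max_lag, floor((n - 1) / 3) - 2))
  best <- NULL
  for (L in 0:max_lag) {
    nn <- length(dx) - L
    Y <- dx[(L + 1):length(dx)]
    X <- cbind(1, x[(L + 1):(n - 1)])
    if (L > 0) {
      for (j in seq_len(L)) {
        X <- cbind(X, dx[(L + 1 - j):(length(dx) - j)])
      }
    }
    fit <- stats::lm.fit(X, Y)
    rss <- sum(fit$residuals^2)
    aic <- nn * log(rss / nn) + 2 * ncol(X)
    if (is.null(best) || aic < best$aic) {
      best <- list(aic = aic, fit = fit, X = X, nn = nn, rss = rss)
    }
  }
  dof <- best$nn - ncol(best$X)
  if (dof <= 0) stop("adf_test: series too short for the chosen lag order")
  s2 <- best$rss / dof
  xtx_inv <- chol2inv(chol(crossprod(best$X)))
  stat <- best$fit$coefficients[2] / sqrt(s2 * xtx_inv[2, 2])
  Tn <- best$nn
  ## MacKinnon (2010) response surface, tau_c at 5%
  cv <- -2.86154 - 2.8903 / Tn - 4.234 / Tn^2 - 40.040 / Tn^3
  list(statistic = unname(stat), critical_value = cv,
       stationary = unname(stat) < cv)
}

#' Select the differencing order by repeated ADF testing
#'
#' Returns the smallest `d` in `1..d_max` whose d-th difference is
#' stationary at the 5% level (1 is the domain floor).  If no difference up
#' to `d_max` passes, `d_max` is returned with a warning.
#'
#' @param x numeric series (length `>= 10`).
#' @param d_max maximum differencing order (default 3).
#' @return integer differencing order.
#' @export
adf_select_d <- function(x, d_max = 3L) {
  for (d in seq_len(d_max)) {
    dx <- diff(x, differences = d)
    if (length(dx) < 10) stop("adf_select_d: series too short after differencing")
    if (adf_test(dx)$stationary) return(as.integer(d))
  }
  warning("adf_select_d: no difference up to d_max is stationary; using d_max")
  as.integer(d_max)
}

#' RSS-based AIC approximation
#'
#' `AIC = n * (log(2 * pi * RSS / n) + 1) + 2 * (p + q)` where `n` is the
#' number of observations entering the fit (after differencing).
#'
#' @param rss residual sum of squares, `> 0`.
#' @param n_obs number of observations, `> 0`.
#' @param p,q autoregressive and moving-average orders.
#' @return AIC value.
#' @export
aic_rss <- function(rss, n_obs, p, q) {
  if (rss <= 0) stop("aic_rss: RSS must be > 0")
  if (n_obs <= 0) stop("aic_rss: n_obs must be > 0")
  n_obs * (log(2 * pi * rss / n_obs) + 1) + 2 * (p + q)
}

#' Fit an ARIMA model by maximum likelihood
#'
#' Wraps `stats::arima` (CSS-ML) and stores the pieces the rest of the
#' pipeline needs: order, coefficients, one-step in-sample residuals, RSS,
#' and the RSS-based AIC.  A drift (linear-trend) regressor is included by
#' default.
#'
#' @param x an [annual_counts] object or numeric vector.
#' @param order integer vector `c(p, d, q)`.
#' @param include_drift include a linear-trend regressor (default `TRUE`).
#' @return an object of class `rc_arima` with elements `order`, `coef`,
#'   `sigma2`, `residuals`, `fitted`, `rss`, `aic_rss`, `loglik`, `aic_mle`,
#'   `n`, `series`, `start_year`, `include_drift`.
#' @export
fit_arima <- function(x, order, include_drift = TRUE) {
  y <- if (inherits(x, "annual_counts")) x$counts else as.numeric(x)
  start_year <- if (inherits(x, "annual_counts")) x$start_year else NA_integer_
  p <- order[1]; d <- order[2]; q <- order[3]
  n <- length(y)
  if (n <= p + q + d + 1) stop("fit_arima: series too short for this order")
  xreg <- if (include_drift) matrix(seq_len(n), ncol = 1,
                                    dimnames = list(NULL, "drift")) else NULL
  fit <- withCallingHandlers(
    stats::arima(y, order = c(p, d, q), xreg = xreg, method = "CSS-ML"),
    warning = function(w) {
      if (grepl("possibly not", conditionMessage(w))) {
        warning(sprintf("arima_boundary: order (%d,%d,%d): %s",
                        p, d, q, conditionMessage(w)), call. = FALSE)
        invokeRestart("muffleWarning")
      }
    })
  ## predict.Arima re-evaluates the xreg expression from the stored call;
  ## embed the matrix itself so prediction works outside this frame
  fit$call$xreg <- xreg
  res <- as.numeric(fit$residuals)
  rss <- sum(res^2)
  structure(list(order = c(p = p, d = d, q = q), coef = stats::coef(fit),
                 sigma2 = fit$sigma2, residuals = res,
                 fitted = y - res, rss = rss,
                 aic_rss = aic_rss(rss, n - d, p, q),
                 loglik = fit$loglik, aic_mle = fit$aic,
                 n = n, series = y, start_year = start_year,
                 include_drift = include_drift, arima = fit),
            class = "rc_arima")
}

#' @export
print.rc_arima <- function(x, ...) {
  cat(sprintf("<rc_arima> ARIMA(%d,%d,%d)%s, n = %d, RSS-AIC = %.2f\n",
              x$order[1], x$order[2], x$order[3],
              if (x$include_drift) " + drift" else "", x$n, x$aic_rss))
  invisible(x)
}

#' Select the ARIMA order by AIC
#'
#' Differencing order `d` is fixed first by [adf_select_d]; `(p, q)` are then
#' chosen to minimise the RSS-based AIC ([aic_rss]).  The default search is
#' the Hyndman-Khandakar stepwise walk used by the common auto-order tools
#' (start from (2,2), (0,0), (1,0), (0,1); move to the best neighbouring
#' order until no improvement).  `stepwise = FALSE` fits every `(p, q)` pair
#' exhaustively; ties break toward smaller `p + q`, then smaller `q`.
#'
#' @param x an [annual_counts] object or numeric vector.
#' @param p_max,q_max,d_max search bounds (defaults 5, 5, 3).
#' @param stepwise use the stepwise walk (default) or the exhaustive grid.
#' @param include_drift passed to [fit_arima].
#' @return list with `order` (named integer vector), `fit` (the winning
#'   `rc_arima`), `n_candidates` (number of `(p, q)` fits attempted), and
#'   `aic_table` (data.frame of all scored candidates).
#' @export
arima_order_search <- function(x, p_max = 5L, q_max = 5L, d_max = 3L,
                               stepwise = TRUE, include_drift = TRUE) {
  y <- if (inherits(x, "annual_counts")) x$counts else as.numeric(x)
  d <- adf_select_d(y, d_max)
  cache <- new.env(parent = emptyenv())
  score <- function(p, q) {
    key <- paste(p, q)
    if (!is.null(cache[[key]])) return(cache[[key]])
    fit <- tryCatch(
      suppressWarnings(fit_arima(x, c(p, d, q), include_drift)),
      error = function(e) NULL)
    val <- list(p = p, q = q, fit = fit,
                aic = if (is.null(fit)) Inf else fit$aic_rss)
    cache[[key]] <- val
    val
  }
  better <- function(a, b) {
    ## a strictly better than b, with ties toward smaller p+q then smaller q
    if (a$aic < b$aic - 1e-12) return(TRUE)
    if (a$aic > b$aic + 1e-12) return(FALSE)
    if (a$p + a$q != b$p + b$q) return(a$p + a$q < b$p + b$q)
    a$q < b$q
  }
  if (stepwise) {
    best <- NULL
    for (s in list(c(2, 2), c(0, 0), c(1, 0), c(0, 1))) {
      if (s[1] > p_max || s[2] > q_max) next
      cand <- score(s[1], s[2])
      if (is.null(best) || better(cand, best)) best <- cand
    }
    repeat {
      improved <- FALSE
      for (step in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                        c(1, 1), c(-1, -1), c(1, -1), c(-1, 1))) {
        p <- best$p + step[1]; q <- best$q + step[2]
        if (p < 0 || q < 0 || p > p_max || q > q_max) next
        cand <- score(p, q)
        if (better(cand, best)) {
          best <- cand; improved <- TRUE; break
        }
      }
      if (!improved) break
    }
  } else {
    best <- NULL
    for (p in 0:p_max) for (q in 0:q_max) {
      cand <- score(p, q)
      if (is.null(best) || better(cand, best)) best <- cand
    }
  }
  if (is.null(best$fit)) stop("arima_order_search: all candidate fits failed")
  scored <- ls(cache)
  tab <- do.call(rbind, lapply(scored, function(k) {
    v <- cache[[k]]
    data.frame(p = v$p, q = v$q, aic = v$aic)
  }))
  list(order = c(p = as.integer(best$p), d = as.integer(d),
                 q = as.integer(best$q)),
       fit = best$fit,
       n_candidates = nrow(tab), aic_table = tab[order(tab$aic), ])
}

#' Forecast from a fitted ARIMA model
#'
#' Point forecasts from the fitted recursion with Gaussian prediction
#' intervals `point +/- z * se(h)` where `se(h)` is the h-step forecast
#' standard error.
#'
#' @param fit an `rc_arima` from [fit_arima].
#' @param h forecast horizon, `>= 1`.
#' @param level interval level in (0, 1), default 0.95.
#' @return data.frame with `h`, `point`, `lower`, `upper`, `se`.
#' @export
forecast_arima <- function(fit, h = 1L, level = 0.95) {
  stopifnot(inherits(fit, "rc_arima"), h >= 1, level > 0, level < 1)
  newxreg <- if (fit$include_drift) {
    matrix(fit$n + seq_len(h), ncol = 1, dimnames = list(NULL, "drift"))
  } else NULL
  pr <- stats::predict(fit$arima, n.ahead = h, newxreg = newxreg)
  z <- stats::qnorm((1 + level) / 2)
  pt <- as.numeric(pr$pred); se <- as.numeric(pr$se)
  data.frame(h = seq_len(h), point = pt,
             lower = pt - z * se, upper = pt + z * se, se = se)
}
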