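## Rolling-origin comparison harness: six model variants (change-point NHPP,
## ARIMA, hybrid with maximum 3/5/7/10 input lags), training windows ending
## T = 2003..2014, RMSE/MAPE on training fits and test forecasts, and the
## five-year future-forecast comparison with and without the 2020 count.

#' Root mean squared error
#'
#' @param actual,predicted equal-length numeric vectors.
#' @return `sqrt(mean((actual - predicted)^2))`.
#' @export
rmse <- function(actual, predicted) {
  if (length(actual) != length(predicted)) stop("rmse: length mismatch")
  sqrt(mean((actual - predicted)^2))
}

#' Mean absolute percentage error
#'
#' `100 * mean(|a - p| / |a|)`.  Zero actual values make the raw definition
#' undefined; the default policy excludes those terms and reports how many
#' were excluded (attribute `n_excluded`), the alternative floors the
#' denominator at `eps`.
#'
#' @param actual,predicted equal-length numeric vectors.
#' @param zero_policy `"exclude"` (default) or `"epsilon_floor"`.
#' @param eps denominator floor for the `"epsilon_floor"` policy.
#' @return MAPE in percent, with attribute `n_excluded`.
#' @export
mape <- function(actual, predicted,
                 zero_policy = c("exclude", "epsilon_floor"), eps = 0.5) {
  if (length(actual) != length(predicted)) stop("mape: length mismatch")
  zero_policy <- match.arg(zero_policy)
  if (zero_policy == "exclude") {
    keep <- actual != 0
    if (!any(keep)) stop("mape: all actual values are zero under exclude policy")
    out <- 100 * mean(abs(actual[keep] - predicted[keep]) /
                        abs(actual[keep]))
    attr(out, "n_excluded") <- sum(!keep)
  } else {
    out <- 100 * mean(abs(actual - predicted) / pmax(abs(actual), eps))
    attr(out, "n_excluded") <- 0L
  }
  out
}

#' Model-variant names used by the evaluation harness
#' @return character vector of the six variant names.
#' @export
variant_names <- function() {
  c("changepoint_wg", "arima", "hybrid_n3", "hybrid_n5", "hybrid_n7",
    "hybrid_n10")
}

.hybrid_nmax <- function(variant) {
  as.integer(sub("^hybrid_n", "", variant))
}

## Default controls for the harness; reduced MCMC/ANN budgets relative to a
## long exploratory run keep a full rolling study on one CPU tractable.
.eval_control <- function(control = list()) {
  utils::modifyList(list(
    mcmc_chains = 4L, mcmc_iterations = 6000L, n_change_points = 1L,
    snc_restarts = 2L, ann_iterations = 2000L, lambda = 0.01, m_max = 10L,
    select_order = TRUE, interval_policy = "shift"
  ), control)
}

## Fit one variant on a training window and return train fits + forecaster.
.fit_variant <- function(variant, train, events, ctl, seed) {
  T_last <- max(train$years)
  if (variant == "arima") {
    fit <- if (ctl$select_order) arima_order_search(train)$fit
           else fit_arima(train, c(0, 1, 1))
    list(fitted = fit$fitted,
         forecast = function(h) forecast_arima(fit, h)$point,
         fit = fit)
  } else if (grepl("^hybrid_n", variant)) {
    fit <- fit_hybrid(train, n_max = .hybrid_nmax(variant),
                      lambda = ctl$lambda,
                      max_iterations = ctl$ann_iterations,
                      restarts = ctl$snc_restarts, m_max = ctl$m_max,
                      seed = seed)
    list(fitted = fit$fitted,
         forecast = function(h) forecast_hybrid(fit, h)$point,
         fit = fit)
  } else if (variant == "changepoint_wg") {
    if (is.null(events)) stop("changepoint_wg requires an event series")
    end_day <- year_start_offset(T_last + 1, events$origin_date)
    ev_tr <- truncate_events(events, end_day)
    spec <- changepoint_spec(end_day,
                             n_change_points = ctl$n_change_points)
    post <- suppressWarnings(
      sample_posterior(ev_tr, spec, n_chains = ctl$mcmc_chains,
                       n_iterations = ctl$mcmc_iterations, seed = seed))
    list(fitted = unname(fitted_annual_means(post, train$years)),
         forecast = function(h) {
           forecast_annual(post, horizon_years = h, seed = seed + 1L)$mean
         },
         fit = post)
  } else {
    stop(sprintf("unknown variant '%s' (valid: %s)", variant,
                 paste(variant_names(), collapse = ", ")))
  }
}

#' Rolling-origin evaluation of the model variants
#'
#' For each training window 1966..T (T in `T_range`) and each variant, fits
#' the model on the training years only (the change-point variant uses the
#' event series truncated at the calendar end of year T), computes training
#' RMSE/MAPE on in-sample fitted values (posterior-mean expected counts for
#' the change-point model) and test RMSE/MAPE on forecasts over the
#' remaining years.  Fully seeded; per-cell fit failures are recorded, not
#' fatal.
#'
#' @param counts an [annual_counts] covering the full study period.
#' @param events an [event_series] (required for the change-point variant).
#' @param variants subset of [variant_names()].
#' @param T_range final training years (default `2003:2014`).
#' @param seed base seed.
#' @param control named list overriding the harness defaults (MCMC chains /
#'   iterations, SNC restarts, ANN iterations, lambda, ...).
#' @return data.frame with one row per variant x T: train/test RMSE and
#'   MAPE, and an `error` column (NA on success).
#' @export
rolling_evaluation <- function(counts, events = NULL,
                               variants = c("arima", "hybrid_n5"),
                               T_range = 2003:2014, seed = 1L,
                               control = list()) {
  stopifnot(inherits(counts, "annual_counts"))
  bad <- setdiff(variants, variant_names())
  if (length(bad)) {
    stop(sprintf("unknown variant '%s' (valid: %s)", bad[1],
                 paste(variant_names(), collapse = ", ")))
  }
  ctl <- .eval_control(control)
  rows <- list()
  for (T_last in T_range) {
    sp <- split_by_year(counts, T_last)
    for (v in variants) {
      row <- data.frame(variant = v, T = T_last, train_rmse = NA_real_,
                        train_mape = NA_real_, test_rmse = NA_real_,
                        test_mape = NA_real_, error = NA_character_)
      res <- tryCatch({
        m <- .fit_variant(v, sp$train, events, ctl,
                          seed = seed + 131L * (T_last - T_range[1]))
        h <- length(sp$test$counts)
        pred <- m$forecast(h)
        row$train_rmse <- rmse(sp$train$counts, m$fitted)
        row$train_mape <- as.numeric(mape(sp$train$counts, m$fitted))
        row$test_rmse <- rmse(sp$test$counts, pred)
        row$test_mape <- as.numeric(mape(sp$test$counts, pred))
        row
      }, error = function(e) {
        row$error <- conditionMessage(e)
        row
      })
      rows[[length(rows) + 1L]] <- res
    }
  }
  do.call(rbind, rows)
}

#' Five-year future forecasts with and without the most recent year
#'
#' Trains every requested variant on the full series (window A) and on the
#' series with the extra most-recent count appended (window B), producing
#' five-year-ahead point forecasts from each window and the one-step 95%
#' prediction interval for the first forecast year of each window.
#'
#' @param counts_a [annual_counts] for window A (e.g. 1966-2019).
#' @param counts_b [annual_counts] for window B (e.g. 1966-2020).
#' @param events an [event_series] (for the change-point variant; forecasts
#'   for window B reuse the same event fixture truncated at its end year).
#' @param variants subset of [variant_names()].
#' @param level interval level (default 0.95).
#' @param seed base seed.
#' @param control harness control list, as in [rolling_evaluation].
#' @return list with `forecasts` (variant, window, year, point) and
#'   `intervals` (variant, window, year, lower, upper).
#' @export
future_forecast_comparison <- function(counts_a, counts_b, events = NULL,
                                       variants = variant_names(),
                                       level = 0.95, seed = 1L,
                                       control = list()) {
  bad <- setdiff(variants, variant_names())
  if (length(bad)) {
    stop(sprintf("unknown variant '%s' (valid: %s)", bad[1],
                 paste(variant_names(), collapse = ", ")))
  }
  ctl <- .eval_control(control)
  fc_rows <- list(); iv_rows <- list()
  for (w in c("A", "B")) {
    cts <- if (w == "A") counts_a else counts_b
    first_fc_year <- max(cts$years) + 1L
    for (v in variants) {
      sd <- seed + ifelse(w == "A", 0L, 17L)
      if (v == "arima") {
        fit <- if (ctl$select_order) arima_order_search(cts)$fit
               else fit_arima(cts, c(0, 1, 1))
        fa <- forecast_arima(fit, h = 5, level = level)
        pts <- fa$point; lo <- fa$lower[1]; up <- fa$upper[1]
      } else if (grepl("^hybrid_n", v)) {
        fit <- fit_hybrid(cts, n_max = .hybrid_nmax(v), lambda = ctl$lambda,
                          max_iterations = ctl$ann_iterations,
                          restarts = ctl$snc_restarts, m_max = ctl$m_max,
                          seed = sd)
        fh <- forecast_hybrid(fit, h = 5, level = level,
                              interval_policy = ctl$interval_policy)
        pts <- fh$point; lo <- fh$lower[1]; up <- fh$upper[1]
      } else if (v == "changepoint_wg") {
        if (is.null(events)) stop("changepoint_wg requires an event series")
        end_day <- year_start_offset(first_fc_year, events$origin_date)
        ev_tr <- truncate_events(events, end_day)
        spec <- changepoint_spec(end_day,
                                 n_change_points = ctl$n_change_points)
        post <- suppressWarnings(
          sample_posterior(ev_tr, spec, n_chains = ctl$mcmc_chains,
                           n_iterations = ctl$mcmc_iterations, seed = sd))
        fc <- forecast_annual(post, horizon_years = 5, level = level,
                              seed = sd + 1L)
        pts <- fc$mean; lo <- fc$lower[1]; up <- fc$upper[1]
      } else {
        stop(sprintf("unknown variant '%s' (valid: %s)", v,
                     paste(variant_names(), collapse = ", ")))
      }
      fc_rows[[length(fc_rows) + 1L]] <- data.frame(
        variant = v, window = w, year = first_fc_year + 0:4, point = pts)
      iv_rows[[length(iv_rows) + 1L]] <- data.frame(
        variant = v, window = w, year = first_fc_year, lower = lo,
        upper = up)
    }
  }
  list(forecasts = do.call(rbind, fc_rows),
       intervals = do.call(rbind, iv_rows))
}

#' Write evaluation outputs and a reproducibility manifest
#'
#' @param metrics data.frame from [rolling_evaluation] (or `NULL`).
#' @param comparison list from [future_forecast_comparison] (or `NULL`).
#' @param out_dir output directory (created if needed).
#' @param seed,control the seed and control list used, recorded verbatim in
#'   the manifest.
#' @return invisibly, the vector of files written.
#' @export
write_report <- function(metrics = NULL, comparison = NULL, out_dir,
                         seed = NULL, control = list()) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("write_report: cannot create output directory")
  }
  files <- character(0)
  if (!is.null(metrics)) {
    f <- file.path(out_dir, "metrics.csv")
    utils::write.csv(metrics, f, row.names = FALSE)
    files <- c(files, f)
  }
  if (!is.null(comparison)) {
    f <- file.path(out_dir, "forecast_comparison.json")
    jsonlite::write_json(comparison, f, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
    files <- c(files, f)
  }
  manifest <- list(
    package = "rarecast",
    version = as.character(utils::packageVersion("rarecast")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = seed,
    control = .eval_control(control)
  )
  f <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, f, auto_unbox = TRUE, digits = NA)
  files <- c(files, f)
  invisible(files)
}
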