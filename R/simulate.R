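## Seeded synthetic-data generators for both data representations used by the
## models: piecewise-NHPP event streams with known Weibull-geometric segment
## parameters, and annual series with an ARIMA(0,1,1)-with-drift linear core
## plus a known nonlinear residual signal.

#' Piecewise-NHPP simulation scenario
#'
#' @param segments list of segments, each `list(params = wg_params(...),
#'   end = <days>)` with strictly increasing end times; the last `end` is the
#'   simulation horizon.
#' @param seed integer seed; all randomness of [simulate_nhpp] flows from it.
#' @return an object of class `nhpp_scenario`.
#' @export
nhpp_scenario <- function(segments, seed) {
  ends <- vapply(segments, `[[`, numeric(1), "end")
  if (any(diff(c(0, ends)) <= 0)) {
    stop("nhpp_scenario: segment end times must be strictly increasing")
  }
  for (s in segments) stopifnot(inherits(s$params, "wg_params"))
  structure(list(segments = segments, total_horizon = ends[length(ends)],
                 seed = as.integer(seed)),
            class = "nhpp_scenario")
}

#' Simulate a piecewise-NHPP event stream by inversion
#'
#' Events are drawn segment by segment with the classical inversion scheme:
#' the next event after time `t` lies at `Lambda^-1(Lambda(t) + E)` with
#' `E ~ Exponential(1)`.  Each segment's rate is evaluated on the global
#' clock (no reset at change points), matching the likelihood convention of
#' the change-point model.  Inversion (rather than thinning) is used because
#' the WG rate is unbounded near `t = 0` when `alpha < 1`.
#'
#' @param scenario an [nhpp_scenario].
#' @param origin_date calendar date of day 0.
#' @return an [event_series] over `[0, total_horizon]`; identical seeds give
#'   identical output.
#' @export
simulate_nhpp <- function(scenario, origin_date = as.Date("1966-08-01")) {
  stopifnot(inherits(scenario, "nhpp_scenario"))
  set.seed(scenario$seed)
  times <- numeric(0)
  seg_start <- 0
  for (seg in scenario$segments) {
    p <- seg$params
    L <- wg_cumulative(p, seg_start)
    repeat {
      L <- L + stats::rexp(1)
      t_next <- wg_cumulative_inverse(p, L)
      if (t_next > seg$end) break
      times <- c(times, t_next)
    }
    seg_start <- seg$end
  }
  event_series(times, origin_date, scenario$total_horizon)
}

## Registry of named nonlinear maps applied to the two most recent
## innovations; fixed so tests can reference scenarios reproducibly.
.nonlinear_registry <- list(
  zero      = function(e1, e2) 0,
  quadratic = function(e1, e2) 0.5 * e1^2,
  sine      = function(e1, e2) sin(e1) * cos(e2),
  threshold = function(e1, e2) ifelse(e1 > 0, 0.8 * e1, -0.2 * e1),
  ## zero linear correlation with either lag, so the signal survives the
  ## ARIMA pre-whitening and genuinely requires both lags to recover
  product   = function(e1, e2) 0.6 * e1 * e2
)

#' Hybrid-series simulation scenario
#'
#' Defines an annual series whose linear core is ARIMA(0,1,1) with drift —
#' the year-over-year increment is
#' `y_t - y_{t-1} = drift + eps_t - theta1 * eps_{t-1} +
#' f(eps_{t-1}, eps_{t-2})` — so the first differences carry an MA(1)
#' signature (lag-1 autocorrelation `-theta1 / (1 + theta1^2)` when `f` is
#' zero) plus a known nonlinear function of lagged innovations for the
#' residual network to recover.
#'
#' @param n_years series length, `>= 10`.
#' @param theta1 moving-average coefficient of the linear core.
#' @param drift per-year trend.
#' @param nonlinear_fn name of a registered map (`"zero"`, `"quadratic"`,
#'   `"sine"`, `"threshold"`, `"product"`).
#' @param noise_sd innovation standard deviation, `>= 0`.
#' @param seed integer seed.
#' @return an object of class `hybrid_scenario`.
#' @export
hybrid_scenario <- function(n_years, theta1 = 0.7, drift = 0.12,
                            nonlinear_fn = "zero", noise_sd = 1.4, seed = 1L) {
  if (n_years < 10) stop("hybrid_scenario: n_years must be >= 10")
  if (noise_sd < 0) stop("hybrid_scenario: noise_sd must be >= 0")
  if (!nonlinear_fn %in% names(.nonlinear_registry)) {
    stop(sprintf("unknown_nonlinear_fn: '%s' (known: %s)", nonlinear_fn,
                 paste(names(.nonlinear_registry), collapse = ", ")))
  }
  structure(list(n_years = as.integer(n_years), theta1 = theta1,
                 drift = drift, nonlinear_fn = nonlinear_fn,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "hybrid_scenario")
}

#' Simulate an annual series with known linear and nonlinear structure
#'
#' @param scenario a [hybrid_scenario].
#' @param start_year first calendar year of the series.
#' @param integer_counts if `TRUE`, round and clip at zero so the output is a
#'   valid count series (for count-model tests); default returns the
#'   real-valued series.
#' @return an [annual_counts] object (real-valued unless `integer_counts`).
#' @export
simulate_hybrid_series <- function(scenario, start_year = 1966L,
                                   integer_counts = FALSE) {
  stopifnot(inherits(scenario, "hybrid_scenario"))
  set.seed(scenario$seed)
  n <- scenario$n_years
  f <- .nonlinear_registry[[scenario$nonlinear_fn]]
  eps <- stats::rnorm(n + 2, 0, scenario$noise_sd)
  t_idx <- seq_len(n)
  incr <- scenario$drift + eps[t_idx + 2] -
    scenario$theta1 * eps[t_idx + 1] +
    mapply(f, eps[t_idx + 1], eps[t_idx])
  y <- cumsum(incr)
  if (integer_counts) y <- pmax(0, round(y))
  ## real-valued series may be negative, so bypass the count validator
  structure(list(counts = y, start_year = as.integer(start_year),
                 years = seq(as.integer(start_year), by = 1L,
                             length.out = n)),
            class = "annual_counts")
}
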