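## Bayesian change-point NHPP with Weibull-geometric intensity.
##
## The observation window [0, observation_end] is divided into k+1 segments
## by ordered change points 0 < tau_1 < ... < tau_k < observation_end; each
## segment carries its own WG parameters (alpha, beta, rho).  Priors are
## uniform over a box, with the change points constrained to be ordered.
## Segments are right-open: an event exactly at tau_j belongs to segment
## j+1.  By default each segment's rate is evaluated on the global clock (no
## reset at change points); `reset_clock = TRUE` restarts time at each
## change point instead.

#' Change-point model specification
#'
#' @param observation_end end of the observation window in days.
#' @param n_change_points number of change points (0, 1 or 2); default 1.
#' @param alpha_max,beta_max,rho_max upper bounds of the uniform priors for
#'   the WG parameters (lower bounds are 0); defaults are weakly informative:
#'   `alpha in (0, 10]`, `beta in (0, 10 * observation_end]`,
#'   `rho in [0, 0.999]`.
#' @param reset_clock if `TRUE`, each segment's rate is evaluated on a clock
#'   restarted at the segment start.
#' @return an object of class `changepoint_spec`.
#' @export
changepoint_spec <- function(observation_end, n_change_points = 1L,
                             alpha_max = 10, beta_max = 10 * observation_end,
                             rho_max = 0.999, reset_clock = FALSE) {
  if (!n_change_points %in% 0:2) {
    stop("changepoint_spec: n_change_points must be 0, 1 or 2")
  }
  stopifnot(observation_end > 0, alpha_max > 0, beta_max > 0,
            rho_max >= 0, rho_max < 1)
  k <- as.integer(n_change_points)
  structure(list(observation_end = as.numeric(observation_end),
                 n_change_points = k,
                 alpha_max = alpha_max, beta_max = beta_max,
                 rho_max = rho_max, reset_clock = isTRUE(reset_clock),
                 n_params = 3L * (k + 1L) + k),
            class = "changepoint_spec")
}

## Parameter-vector layout: (alpha_1, beta_1, rho_1, ..., alpha_{k+1},
## beta_{k+1}, rho_{k+1}, tau_1, ..., tau_k).
.cp_par_names <- function(spec) {
  k <- spec$n_change_points
  c(paste0(rep(c("alpha", "beta", "rho"), k + 1),
           rep(seq_len(k + 1), each = 3)),
    if (k > 0) paste0("tau", seq_len(k)))
}

.cp_unpack <- function(spec, theta) {
  k <- spec$n_change_points
  P <- matrix(theta[seq_len(3 * (k + 1))], ncol = 3, byrow = TRUE)
  taus <- if (k > 0) theta[3 * (k + 1) + seq_len(k)] else numeric(0)
  list(P = P, taus = taus)
}

.cp_in_support <- function(spec, theta) {
  u <- .cp_unpack(spec, theta)
  if (any(!is.finite(theta))) return(FALSE)
  if (any(u$P[, 1] <= 0 | u$P[, 1] > spec$alpha_max)) return(FALSE)
  if (any(u$P[, 2] <= 0 | u$P[, 2] > spec$beta_max)) return(FALSE)
  if (any(u$P[, 3] < 0 | u$P[, 3] > spec$rho_max)) return(FALSE)
  if (spec$n_change_points > 0 &&
      any(diff(c(0, u$taus, spec$observation_end)) <= 0)) return(FALSE)
  TRUE
}

## log rate, vectorised over t (t > 0)
.wg_lrate <- function(a, b, r, t) {
  log(a / b) + (a - 1) * log(t / b) - log1p(-r * exp(-(t / b)^a))
}
.wg_Lam <- function(a, b, r, t) {
  u <- (t / b)^a
  u + log1p(-r * exp(-u)) - log1p(-r)
}

#' NHPP change-point log-likelihood
#'
#' `sum_i log lambda_active(t_i) - sum_j [Lambda_j(end_j) - Lambda_j(start_j)]`
#' where the active segment is the right-open segment containing each event.
#' An event exactly at time 0 is treated as the process origin and excluded
#' from the point sum (the WG rate diverges there when `alpha < 1`).
#'
#' @param events an [event_series].
#' @param spec a [changepoint_spec].
#' @param params list of [wg_params], one per segment (`k + 1` entries).
#' @param change_points ordered change points (length `k`).
#' @return log-likelihood (scalar; `-Inf` outside the prior support).
#' @export
nhpp_loglik <- function(events, spec, params, change_points = numeric(0)) {
  stopifnot(inherits(events, "event_series"),
            inherits(spec, "changepoint_spec"))
  if (length(params) != spec$n_change_points + 1L) {
    stop("nhpp_loglik: need one wg_params per segment")
  }
  theta <- c(vapply(params, function(p) c(p$alpha, p$beta, p$rho),
                    numeric(3)), change_points)
  .cp_loglik(theta, spec, events$event_times[events$event_times > 0])
}

## theta-level likelihood used by the sampler (t: positive event times)
.cp_loglik <- function(theta, spec, t) {
  if (!.cp_in_support(spec, theta)) return(-Inf)
  u <- .cp_unpack(spec, theta)
  bnd <- c(0, u$taus, spec$observation_end)
  ll <- 0
  for (j in seq_len(nrow(u$P))) {
    a <- u$P[j, 1]; b <- u$P[j, 2]; r <- u$P[j, 3]
    lo <- bnd[j]; hi <- bnd[j + 1]
    sel <- if (j == nrow(u$P)) t >= lo & t <= hi else t >= lo & t < hi
    if (spec$reset_clock) {
      ts <- t[sel] - lo
      ts <- ts[ts > 0]
      ll <- ll + sum(.wg_lrate(a, b, r, ts)) + .wg_Lam(a, b, r, 0) -
        .wg_Lam(a, b, r, hi - lo)
    } else {
      ll <- ll + sum(.wg_lrate(a, b, r, t[sel])) -
        (.wg_Lam(a, b, r, hi) - .wg_Lam(a, b, r, lo))
    }
    if (!is.finite(ll)) return(-Inf)
  }
  ll
}

## Split-chain R-hat (potential scale reduction) per parameter.
.split_rhat <- function(draws_by_chain) {
  halves <- list()
  for (d in draws_by_chain) {
    n <- nrow(d)
    h <- floor(n / 2)
    halves <- c(halves, list(d[seq_len(h), , drop = FALSE],
                             d[(n - h + 1):n, , drop = FALSE]))
  }
  n <- nrow(halves[[1]])
  m <- length(halves)
  means <- vapply(halves, colMeans, numeric(ncol(halves[[1]])))
  vars <- vapply(halves, function(h) apply(h, 2, stats::var),
                 numeric(ncol(halves[[1]])))
  means <- matrix(means, ncol = m)
  vars <- matrix(vars, ncol = m)
  B <- n * apply(means, 1, stats::var)
  W <- rowMeans(vars)
  sqrt(((n - 1) / n * W + B / n) / W)
}

## Effective sample size per parameter (Geyer initial positive sequence,
## averaged over chains).
.ess <- function(draws_by_chain) {
  p <- ncol(draws_by_chain[[1]])
  n <- nrow(draws_by_chain[[1]])
  m <- length(draws_by_chain)
  vapply(seq_len(p), function(j) {
    rho_sum <- 0
    for (d in draws_by_chain) {
      x <- d[, j]
      if (stats::var(x) == 0) next
      ac <- stats::acf(x, lag.max = min(n - 2, 200), plot = FALSE,
                       demean = TRUE)$acf[-1]
      s <- 0
      for (k in seq(1, length(ac) - 1, by = 2)) {
        pair <- ac[k] + ac[k + 1]
        if (is.na(pair) || pair < 0) break
        s <- s + pair
      }
      rho_sum <- rho_sum + s
    }
    rho_bar <- rho_sum / m
    m * n / (1 + 2 * rho_bar)
  }, numeric(1))
}

#' Sample the change-point posterior by adaptive random-walk Metropolis
#'
#' Runs `n_chains` independent chains with over-dispersed uniform starting
#' points, coordinate-wise Gaussian random-walk proposals, and per-coordinate
#' step-size adaptation during warm-up only (frozen afterwards, so the
#' retained draws target the exact posterior).  The posterior is proportional
#' to the NHPP likelihood times the uniform box prior with ordered change
#' points.
#'
#' @param events an [event_series].
#' @param spec a [changepoint_spec].
#' @param n_chains number of chains (default 4).
#' @param n_iterations iterations per chain including warm-up.  The default
#'   is sized so that a fixture-scale fit with one change point reaches
#'   split R-hat below 1.05; simpler fits (no change point) converge with
#'   far fewer.
#' @param warmup warm-up iterations discarded from each chain.
#' @param seed integer seed; identical seeds give identical draws.
#' @param prior_only if `TRUE`, sample the prior (likelihood switched off).
#' @param n_rungs tempering rungs per chain (default 4, inverse temperatures
#'   `(1/3)^(0..n_rungs-1)`).  The change-point posterior is typically
#'   multimodal in tau; hot replicas cross between modes and adjacent-rung
#'   swaps propagate those jumps to the cold (target) replica.  Set to 1 for
#'   plain random-walk Metropolis.
#' @return an object of class `cp_posterior`: `draws` (matrix, one row per
#'   retained draw, with a `chain` attribute column), `rhat` and `ess` per
#'   parameter, per-chain acceptance rates, and `converged`
#'   (all `rhat <= 1.05`).  Non-convergence flags the result; it never
#'   throws.
#' @export
sample_posterior <- function(events, spec, n_chains = 4L,
                             n_iterations = 150000L,
                             warmup = floor(n_iterations / 2),
                             seed = 1L, prior_only = FALSE, n_rungs = 4L) {
  stopifnot(inherits(events, "event_series"),
            inherits(spec, "changepoint_spec"))
  set.seed(seed)
  t_pos <- events$event_times[events$event_times > 0 &
                              events$event_times <= spec$observation_end]
  k <- spec$n_change_points

  if (prior_only) n_rungs <- 1L
  chains <- vector("list", n_chains)
  acc_rates <- numeric(n_chains)
  for (ch in seq_len(n_chains)) {
    res <- cp_run_chain(t_pos, spec$observation_end, k, spec$reset_clock,
                        spec$alpha_max, spec$beta_max, spec$rho_max,
                        as.integer(n_iterations), as.integer(warmup),
                        as.integer(n_rungs), prior_only)
    keep <- res$draws
    colnames(keep) <- .cp_par_names(spec)
    chains[[ch]] <- keep
    acc_rates[ch] <- res$acceptance
  }
  rhat <- .split_rhat(chains)
  ess <- .ess(chains)
  names(rhat) <- names(ess) <- .cp_par_names(spec)
  draws <- do.call(rbind, chains)
  res <- structure(list(draws = draws,
                        chain = rep(seq_len(n_chains),
                                    each = n_iterations - warmup),
                        spec = spec, events = events,
                        acceptance = acc_rates, rhat = rhat, ess = ess,
                        converged = all(rhat <= 1.05, na.rm = TRUE),
                        seed = seed),
                   class = "cp_posterior")
  if (!res$converged) {
    warning(sprintf("mcmc_not_converged: max split R-hat = %.3f",
                    max(rhat, na.rm = TRUE)))
  }
  res
}

#' @export
print.cp_posterior <- function(x, ...) {
  cat(sprintf(
    "<cp_posterior> %d draws x %d params (%d chains), max R-hat %.3f%s\n",
    nrow(x$draws), ncol(x$draws), max(x$chain), max(x$rhat, na.rm = TRUE),
    if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

## Expected count of one draw on [t0, t1] (handles segment overlap)
.cp_expected_count <- function(spec, theta, t0, t1) {
  u <- .cp_unpack(spec, theta)
  bnd <- c(0, u$taus, Inf)
  total <- 0
  for (j in seq_len(nrow(u$P))) {
    lo <- max(t0, bnd[j]); hi <- min(t1, bnd[j + 1])
    if (hi <= lo) next
    a <- u$P[j, 1]; b <- u$P[j, 2]; r <- u$P[j, 3]
    if (spec$reset_clock) {
      total <- total + .wg_Lam(a, b, r, hi - bnd[j]) -
        .wg_Lam(a, b, r, lo - bnd[j])
    } else {
      total <- total + .wg_Lam(a, b, r, hi) - .wg_Lam(a, b, r, lo)
    }
  }
  total
}

#' Posterior-mean expected annual counts over the observation window
#'
#' For each retained draw, the expected count in calendar year `y` is the
#' cumulative-intensity increment over that year's day window (split across
#' segments as needed); the posterior mean per year is returned.
#'
#' @param posterior a `cp_posterior` from [sample_posterior].
#' @param years calendar years, all inside the observation window.
#' @param max_draws optional cap on the number of draws used (thinned
#'   evenly); `NULL` uses all draws.
#' @return named numeric vector of posterior-mean expected counts.
#' @export
fitted_annual_means <- function(posterior, years, max_draws = 2000L) {
  stopifnot(inherits(posterior, "cp_posterior"))
  ev <- posterior$events
  spec <- posterior$spec
  dr <- posterior$draws
  if (!is.null(max_draws) && nrow(dr) > max_draws) {
    dr <- dr[round(seq(1, nrow(dr), length.out = max_draws)), , drop = FALSE]
  }
  w <- vapply(years, function(y) {
    c(year_start_offset(y, ev$origin_date),
      year_start_offset(y + 1, ev$origin_date))
  }, numeric(2))
  w[1, ] <- pmax(w[1, ], 0)
  w[2, ] <- pmin(w[2, ], spec$observation_end)
  if (any(w[2, ] <= w[1, ])) {
    stop("fitted_annual_means: year outside the observation window")
  }
  out <- vapply(seq_along(years), function(i) {
    mean(apply(dr, 1, function(th) {
      .cp_expected_count(spec, th, w[1, i], w[2, i])
    }))
  }, numeric(1))
  names(out) <- years
  out
}

#' Posterior-predictive annual forecast from the change-point model
#'
#' For each retained draw (times `n_sims_per_draw`), the NHPP is simulated
#' forward from the end of the observation window by inversion of the final
#' segment's cumulative intensity, the simulated events are binned into
#' calendar years, and per-year means plus equal-tailed interval bounds are
#' taken across simulations.  Bounds are order statistics of the simulated
#' integer counts, so they are integers.
#'
#' @param posterior a `cp_posterior`.
#' @param horizon_years number of forecast years.
#' @param n_sims_per_draw NHPP simulations per posterior draw.
#' @param level interval level in (0, 1).
#' @param seed integer seed for the forward simulation.
#' @param max_draws optional cap on the number of posterior draws used
#'   (thinned evenly); `NULL` uses all draws.
#' @return a data.frame with `year`, `mean`, `lower`, `upper`.
#' @export
forecast_annual <- function(posterior, horizon_years = 1L,
                            n_sims_per_draw = 1L, level = 0.95, seed = 1L,
                            max_draws = 4000L) {
  stopifnot(inherits(posterior, "cp_posterior"),
            horizon_years >= 1, level > 0, level < 1)
  set.seed(seed)
  ev <- posterior$events
  spec <- posterior$spec
  t_end <- spec$observation_end
  origin <- ev$origin_date
  first_year <- as.integer(format(origin + ceiling(t_end), "%Y"))
  if (year_start_offset(first_year, origin) < t_end) {
    first_year <- first_year + 1L
  }
  years <- first_year + 0:(horizon_years - 1L)
  ybnd <- vapply(c(years, years[horizon_years] + 1L), year_start_offset,
                 numeric(1), origin_date = origin)
  sim_end <- ybnd[horizon_years + 1]

  dr <- posterior$draws
  if (!is.null(max_draws) && nrow(dr) > max_draws) {
    dr <- dr[round(seq(1, nrow(dr), length.out = max_draws)), , drop = FALSE]
  }
  k <- spec$n_change_points
  last <- 3 * k + 1
  n_total <- nrow(dr) * n_sims_per_draw
  counts <- matrix(0L, n_total, horizon_years)
  row <- 0L
  for (m in seq_len(nrow(dr))) {
    p <- wg_params(dr[m, last], dr[m, last + 1], dr[m, last + 2])
    t0 <- if (spec$reset_clock && k > 0) t_end - dr[m, 3 * (k + 1) + k]
          else t_end
    off <- t_end - t0
    for (s in seq_len(n_sims_per_draw)) {
      row <- row + 1L
      L <- wg_cumulative(p, t0)
      t_cur <- t0
      while (TRUE) {
        L <- L + stats::rexp(1)
        t_cur <- wg_cumulative_inverse(p, L)
        if (t_cur + off > sim_end) break
        yi <- findInterval(t_cur + off, ybnd)
        if (yi >= 1 && yi <= horizon_years) {
          counts[row, yi] <- counts[row, yi] + 1L
        }
      }
    }
  }
  a <- (1 - level) / 2
  data.frame(
    year = years,
    mean = colMeans(counts),
    lower = apply(counts, 2, stats::quantile, probs = a, type = 1),
    upper = apply(counts, 2, stats::quantile, probs = 1 - a, type = 1)
  )
}
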