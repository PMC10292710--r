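## Weibull-geometric (WG) intensity for a non-homogeneous Poisson process.
##
## lambda(t) = (alpha/beta) (t/beta)^(alpha-1) / (1 - rho exp(-(t/beta)^alpha))
## Lambda(t) = (t/beta)^alpha + log[(1 - rho exp(-(t/beta)^alpha)) / (1 - rho)]
##
## rho = 0 degenerates to the Weibull (power-law) intensity; alpha = 1 and
## rho = 0 give a homogeneous Poisson process of rate 1/beta.

#' Weibull-geometric rate-function parameters
#'
#' @param alpha shape, `> 0`.  `alpha < 1` gives a rate diverging at `t = 0`;
#'   `alpha > 1` an increasing-at-origin rate.
#' @param beta scale in days, `> 0`.
#' @param rho geometric mixing parameter in `[0, 1)`; `rho = 0` is the plain
#'   Weibull intensity.
#' @return an object of class `wg_params`.
#' @export
wg_params <- function(alpha, beta, rho = 0) {
  if (!is.finite(alpha) || alpha <= 0) stop("wg_params: alpha must be > 0")
  if (!is.finite(beta) || beta <= 0) stop("wg_params: beta must be > 0")
  if (!is.finite(rho) || rho < 0 || rho >= 1) {
    stop("wg_params: rho must lie in [0, 1)")
  }
  structure(list(alpha = alpha, beta = beta, rho = rho),
            class = "wg_params")
}

#' Weibull-geometric rate at time t
#'
#' @param params a [wg_params] object.
#' @param t time(s) in days, `> 0` (`t = 0` allowed only when `alpha >= 1`).
#' @return rate per day, strictly positive (vectorised over `t`).
#' @export
wg_rate <- function(params, t) {
  stopifnot(inherits(params, "wg_params"))
  if (any(t < 0)) stop("wg_rate: negative time")
  if (params$alpha < 1 && any(t == 0)) {
    stop("wg_rate: rate diverges at t = 0 when alpha < 1")
  }
  with(params, {
    u <- (t / beta)^alpha
    (alpha / beta) * (t / beta)^(alpha - 1) / (1 - rho * exp(-u))
  })
}

#' Cumulative WG intensity on [0, t]
#'
#' The closed-form integral of [wg_rate]; equals the expected event count of
#' the NHPP on `[0, t]`.
#'
#' @inheritParams wg_rate
#' @param t time(s) in days, `>= 0`.
#' @return expected count(s), non-negative and non-decreasing in `t`.
#' @export
wg_cumulative <- function(params, t) {
  stopifnot(inherits(params, "wg_params"))
  if (any(t < 0)) stop("wg_cumulative: negative time")
  with(params, {
    u <- (t / beta)^alpha
    u + log1p(-rho * exp(-u)) - log1p(-rho)
  })
}

#' Inverse of the cumulative WG intensity
#'
#' Solves `Lambda(t) = target` for `t`.  Used by the inversion sampler: with
#' `E ~ Exponential(1)`, the next event after `t0` sits at
#' `Lambda^-1(Lambda(t0) + E)`.
#'
#' @inheritParams wg_rate
#' @param target cumulative-intensity value(s), `>= 0`.
#' @return time(s) `t` with `wg_cumulative(params, t) == target`.
#' @export
wg_cumulative_inverse <- function(params, target) {
  stopifnot(inherits(params, "wg_params"))
  if (any(target < 0)) stop("wg_cumulative_inverse: negative target")
  vapply(target, function(L) {
    if (L == 0) return(0)
    ## Solve in u = (t/beta)^alpha: g(u) = u + log1p(-rho e^-u) - log1p(-rho).
    ## g is increasing with g(u) <= u, so u = L is a lower bracket end.
    g <- function(u) u + log1p(-params$rho * exp(-u)) - log1p(-params$rho) - L
    hi <- max(L, 1)
    while (g(hi) < 0) hi <- hi * 2
    u <- stats::uniroot(g, c(0, hi), tol = 1e-12)$root
    params$beta * u^(1 / params$alpha)
  }, numeric(1))
}
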