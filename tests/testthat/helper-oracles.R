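# Shared test helpers: independent oracles and small generators.

# Quadrature oracle for the cumulative WG intensity.
quad_Lambda <- function(params, t) {
  if (t == 0) return(0)
  stats::integrate(function(u) wg_rate(params, u), 0, t,
                   rel.tol = 1e-10, subdivisions = 500L)$value
}

# Random valid WG parameters (alpha kept >= 1 when the integrand must be
# evaluated at 0).
random_wg <- function(alpha_min = 1) {
  wg_params(alpha = runif(1, alpha_min, 4), beta = runif(1, 50, 2000),
            rho = runif(1, 0, 0.95))
}

# Residual-like series with genuine two-lag structure for SNC tests.
gen_two_lag_residuals <- function(n, seed, sd = 0.3) {
  set.seed(seed)
  e <- numeric(n)
  e[1:2] <- rnorm(2, 0, sd)
  for (t in 3:n) {
    e[t] <- 0.4 * e[t - 1] - 0.5 * e[t - 2] + 0.25 * e[t - 2]^2 +
      rnorm(1, 0, sd)
  }
  e
}

# Flatten a weight list to a vector and back, for finite-difference checks.
weights_to_vec <- function(w) c(w$W1, w$b1, w$W2, w$b2)
vec_to_weights <- function(v, w) {
  m <- w$arch$m_hidden; n <- w$arch$n_inputs
  i <- 0
  w$W1 <- matrix(v[seq_len(m * n)], m, n); i <- m * n
  w$b1 <- v[i + seq_len(m)]; i <- i + m
  w$W2 <- matrix(v[i + seq_len(m)], 1, m); i <- i + m
  w$b2 <- v[i + 1]
  w
}
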