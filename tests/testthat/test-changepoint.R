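# Fixture-scale objects shared across blocks
.ev_fix <- mass_shooting_events()
.end2019 <- rarecast:::year_start_offset(2020, .ev_fix$origin_date)

test_that("the likelihood reduces to the homogeneous Poisson closed form", {
  # alpha = 1, rho = 0: N log(1/beta) - T/beta (t = 0 event excluded)
  ev <- event_series(c(0, 120, 340, 700, 950), "1966-08-01",
                     observation_end = 1000)
  spec <- changepoint_spec(1000, n_change_points = 0)
  ll <- nhpp_loglik(ev, spec, list(wg_params(1, 100, 0)))
  expect_equal(ll, 4 * log(1 / 100) - 1000 / 100, tolerance = 1e-12)
})

test_that("the likelihood matches a quadrature-based brute force", {
  set.seed(7)
  ev <- simulate_nhpp(nhpp_scenario(
    list(list(params = wg_params(1.4, 300, 0.4), end = 3000)), seed = 3))
  for (i in 1:5) {
    p1 <- random_wg(); p2 <- random_wg()
    tau <- runif(1, 500, 2500)
    spec <- changepoint_spec(3000, n_change_points = 1)
    ll <- nhpp_loglik(ev, spec, list(p1, p2), tau)
    t <- ev$event_times[ev$event_times > 0]
    brute <- sum(log(wg_rate(p1, t[t < tau]))) +
      sum(log(wg_rate(p2, t[t >= tau]))) -
      quad_Lambda(p1, tau) -
      (quad_Lambda(p2, 3000) - quad_Lambda(p2, tau))
    expect_equal(ll, brute, tolerance = 1e-6)
  }
})

test_that("a change point with identical segment parameters is a no-op", {
  ev <- truncate_events(.ev_fix, .end2019)
  p <- wg_params(1.8, 1200, 0.7)
  s0 <- changepoint_spec(.end2019, n_change_points = 0)
  s1 <- changepoint_spec(.end2019, n_change_points = 1)
  expect_equal(nhpp_loglik(ev, s1, list(p, p), 9000),
               nhpp_loglik(ev, s0, list(p)), tolerance = 1e-10)
})

test_that("the compiled likelihood agrees with the reference implementation", {
  ev <- truncate_events(.ev_fix, .end2019)
  set.seed(11)
  for (k in 0:2) {
    spec <- changepoint_spec(.end2019, n_change_points = k)
    for (i in 1:5) {
      params <- lapply(seq_len(k + 1), function(j) random_wg())
      taus <- sort(runif(k, 1000, .end2019 - 1000))
      theta <- c(vapply(params, function(p) c(p$alpha, p$beta, p$rho),
                        numeric(3)), taus)
      ll_r <- nhpp_loglik(ev, spec, params, taus)
      ll_c <- rarecast:::cp_loglik_cpp(
        theta, ev$event_times[ev$event_times > 0], .end2019, k, FALSE,
        spec$alpha_max, spec$beta_max, spec$rho_max)
      expect_equal(ll_c, ll_r, tolerance = 1e-8)
    }
  }
})

test_that("posterior sampling is seed-deterministic and bound-respecting", {
  ev <- truncate_events(.ev_fix, .end2019)
  spec <- changepoint_spec(.end2019, n_change_points = 1)
  p1 <- suppressWarnings(sample_posterior(ev, spec, n_chains = 2,
                                          n_iterations = 1500, seed = 42))
  p2 <- suppressWarnings(sample_posterior(ev, spec, n_chains = 2,
                                          n_iterations = 1500, seed = 42))
  expect_identical(p1$draws, p2$draws)
  expect_named(p1$rhat)
  expect_length(p1$ess, spec$n_params)

  d <- p1$draws
  expect_true(all(d[, "alpha1"] > 0 & d[, "alpha1"] <= spec$alpha_max))
  expect_true(all(d[, "rho2"] >= 0 & d[, "rho2"] <= spec$rho_max))
  expect_true(all(d[, "tau1"] > 0 & d[, "tau1"] < .end2019))
})

test_that("prior-only sampling recovers the uniform box", {
  ev <- truncate_events(.ev_fix, .end2019)
  spec <- changepoint_spec(.end2019, n_change_points = 0)
  post <- suppressWarnings(
    sample_posterior(ev, spec, n_chains = 1, n_iterations = 40000,
                     seed = 9, prior_only = TRUE))
  thin <- post$draws[seq(1, nrow(post$draws), by = 25), ]
  ks_a <- stats::ks.test(thin[, "alpha1"], "punif", 0, spec$alpha_max)
  ks_b <- stats::ks.test(thin[, "beta1"], "punif", 0, spec$beta_max)
  expect_gt(ks_a$p.value, 0.01)
  expect_gt(ks_b$p.value, 0.01)
})

test_that("posterior intervals recover known simulation parameters", {
  # 20 replicates of a 300-event stream; 95% intervals should cover the
  # truth about 19 times out of 20 -- require at least 90%
  cov_alpha <- 0; cov_beta <- 0
  for (r in 1:20) {
    sc <- nhpp_scenario(list(list(params = wg_params(1.5, 200, 0.5),
                                  end = 9000)), seed = 100 + r)
    sim <- simulate_nhpp(sc)
    spec <- changepoint_spec(9000, n_change_points = 0)
    post <- suppressWarnings(
      sample_posterior(sim, spec, n_chains = 2, n_iterations = 8000,
                       seed = r, n_rungs = 1))
    qa <- stats::quantile(post$draws[, "alpha1"], c(0.025, 0.975))
    qb <- stats::quantile(post$draws[, "beta1"], c(0.025, 0.975))
    cov_alpha <- cov_alpha + (qa[1] <= 1.5 && 1.5 <= qa[2])
    cov_beta <- cov_beta + (qb[1] <= 200 && 200 <= qb[2])
  }
  expect_gte(cov_alpha, 18)
  expect_gte(cov_beta, 18)
})

# A degenerate posterior (all draws identical) built directly, so the
# fitted/forecast operations can be checked against closed forms.
.make_degenerate_post <- function(theta, spec, events, n = 10) {
  draws <- matrix(rep(theta, each = n), n, length(theta))
  colnames(draws) <- rarecast:::.cp_par_names(spec)
  structure(list(draws = draws, chain = rep(1L, n), spec = spec,
                 events = events, acceptance = 1,
                 rhat = rep(1, length(theta)),
                 ess = rep(n, length(theta)), converged = TRUE, seed = 0L),
            class = "cp_posterior")
}

test_that("fitted annual means match the homogeneous closed form", {
  ev <- truncate_events(.ev_fix, .end2019)
  spec <- changepoint_spec(.end2019, n_change_points = 0)
  # rate 1/36.525 per day -> about 10 events per year
  post <- .make_degenerate_post(c(1, 36.525, 0), spec, ev)
  fm <- fitted_annual_means(post, 1970:1975)
  expect_true(all(abs(fm - 10) < 0.05))
  expect_error(fitted_annual_means(post, 2021), "outside")

  # and against the quadrature oracle for a non-trivial parameter set
  post2 <- .make_degenerate_post(c(1.7, 2500, 0.6), spec, ev)
  fm2 <- fitted_annual_means(post2, 2000)
  p <- wg_params(1.7, 2500, 0.6)
  y0 <- rarecast:::year_start_offset(2000, ev$origin_date)
  y1 <- rarecast:::year_start_offset(2001, ev$origin_date)
  expect_equal(unname(fm2), quad_Lambda(p, y1) - quad_Lambda(p, y0),
               tolerance = 1e-6)
})

test_that("degenerate-posterior forecasts follow the Poisson closed form", {
  ev <- truncate_events(.ev_fix, .end2019)
  spec <- changepoint_spec(.end2019, n_change_points = 0)
  # 1/73.05 per day -> 5 per year; annual counts are Poisson(5)
  post <- .make_degenerate_post(c(1, 73.05, 0), spec, ev)
  fc <- forecast_annual(post, horizon_years = 1, n_sims_per_draw = 400,
                        level = 0.95, seed = 21)
  expect_identical(fc$year, 2020L)
  expect_lt(abs(fc$mean - 5), 0.15)
  expect_identical(fc$lower, stats::qpois(0.025, 5))
  expect_identical(fc$upper, stats::qpois(0.975, 5))

  # interval nesting in the level
  fc50 <- forecast_annual(post, horizon_years = 1, n_sims_per_draw = 400,
                          level = 0.50, seed = 21)
  expect_gte(fc50$lower, fc$lower)
  expect_lte(fc50$upper, fc$upper)
  expect_true(fc$lower <= fc$mean && fc$mean <= fc$upper)
})
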