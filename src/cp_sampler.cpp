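// Compiled core of the change-point NHPP sampler: Weibull-geometric
// log-likelihood and one tempered adaptive random-walk Metropolis chain.
// All randomness comes from R's RNG, so seeding via set.seed() in R makes
// runs exactly reproducible.

#include <Rcpp.h>
using namespace Rcpp;

static double wg_Lam(double a, double b, double r, double t) {
  double u = std::pow(t / b, a);
  return u + std::log1p(-r * std::exp(-u)) - std::log1p(-r);
}

static double wg_lrate(double a, double b, double r, double t) {
  return std::log(a / b) + (a - 1.0) * std::log(t / b) -
         std::log1p(-r * std::exp(-std::pow(t / b, a)));
}

// theta layout: (alpha, beta, rho) per segment, then ordered taus
static bool cp_in_support(const std::vector<double>& th, double t_end,
                          int k, double amax, double bmax, double rmax) {
  int nseg = k + 1;
  for (int j = 0; j < nseg; ++j) {
    double a = th[3 * j], b = th[3 * j + 1], r = th[3 * j + 2];
    if (!(a > 0 && a <= amax && b > 0 && b <= bmax && r >= 0 && r <= rmax))
      return false;
  }
  double prev = 0.0;
  for (int j = 0; j < k; ++j) {
    double tau = th[3 * nseg + j];
    if (!(tau > prev && tau < t_end)) return false;
    prev = tau;
  }
  return true;
}

static double cp_loglik_impl(const std::vector<double>& th,
                             const std::vector<double>& t, double t_end,
                             int k, bool reset, double amax, double bmax,
                             double rmax) {
  if (!cp_in_support(th, t_end, k, amax, bmax, rmax)) return R_NegInf;
  int nseg = k + 1;
  double ll = 0.0;
  size_t idx = 0, n = t.size();
  for (int j = 0; j < nseg; ++j) {
    double lo = (j == 0) ? 0.0 : th[3 * nseg + j - 1];
    double hi = (j == k) ? t_end : th[3 * nseg + j];
    double a = th[3 * j], b = th[3 * j + 1], r = th[3 * j + 2];
    // segments are right-open; the last one includes t_end
    while (idx < n && (j == k ? t[idx] <= hi : t[idx] < hi)) {
      double tt = reset ? t[idx] - lo : t[idx];
      if (tt > 0) ll += wg_lrate(a, b, r, tt);
      ++idx;
    }
    if (reset)
      ll -= wg_Lam(a, b, r, hi - lo);
    else
      ll -= wg_Lam(a, b, r, hi) - wg_Lam(a, b, r, lo);
    if (!std::isfinite(ll)) return R_NegInf;
  }
  return ll;
}

// [[Rcpp::export]]
double cp_loglik_cpp(NumericVector theta, NumericVector event_times,
                     double t_end, int k, bool reset_clock, double alpha_max,
                     double beta_max, double rho_max) {
  std::vector<double> th(theta.begin(), theta.end());
  std::vector<double> t(event_times.begin(), event_times.end());
  return cp_loglik_impl(th, t, t_end, k, reset_clock, alpha_max, beta_max,
                        rho_max);
}

// One tempered chain.  Rungs run at inverse temperatures beta_r; coordinate
// updates are Gaussian random walks with a 10% mixture of independent
// uniform-prior draws; one adjacent-rung swap is attempted per iteration;
// per-coordinate step sizes adapt during warm-up only.
// [[Rcpp::export]]
List cp_run_chain(NumericVector event_times, double t_end, int k,
                  bool reset_clock, double alpha_max, double beta_max,
                  double rho_max, int n_iterations, int warmup, int n_rungs,
                  bool prior_only) {
  RNGScope scope;
  std::vector<double> t(event_times.begin(), event_times.end());
  const int nseg = k + 1, d = 3 * nseg + k;

  std::vector<double> lo(d), hi(d);
  for (int j = 0; j < nseg; ++j) {
    lo[3 * j] = 0.0;     hi[3 * j] = alpha_max;
    lo[3 * j + 1] = 0.0; hi[3 * j + 1] = beta_max;
    lo[3 * j + 2] = 0.0; hi[3 * j + 2] = rho_max;
  }
  for (int j = 0; j < k; ++j) {
    lo[3 * nseg + j] = 0.0;
    hi[3 * nseg + j] = t_end;
  }

  auto target = [&](const std::vector<double>& th) -> double {
    if (prior_only)
      return cp_in_support(th, t_end, k, alpha_max, beta_max, rho_max)
                 ? 0.0 : R_NegInf;
    return cp_loglik_impl(th, t, t_end, k, reset_clock, alpha_max, beta_max,
                          rho_max);
  };

  std::vector<double> betas(n_rungs);
  for (int r = 0; r < n_rungs; ++r) betas[r] = std::pow(1.0 / 3.0, r);

  // over-dispersed starts: uniform in the central 90% of the box
  std::vector<std::vector<double>> TH(n_rungs, std::vector<double>(d));
  std::vector<double> LL(n_rungs);
  for (int r = 0; r < n_rungs; ++r) {
    for (int tries = 0; tries < 10000; ++tries) {
      for (int j = 0; j < d; ++j)
        TH[r][j] = lo[j] + (0.05 + 0.9 * unif_rand()) * (hi[j] - lo[j]);
      if (k > 0) std::sort(TH[r].begin() + 3 * nseg, TH[r].end());
      LL[r] = target(TH[r]);
      if (std::isfinite(LL[r])) break;
    }
    if (!std::isfinite(LL[r])) stop("cp_run_chain: cannot initialise chain");
  }

  std::vector<std::vector<double>> SC(n_rungs, std::vector<double>(d));
  for (int r = 0; r < n_rungs; ++r)
    for (int j = 0; j < d; ++j) SC[r][j] = 0.05 * (hi[j] - lo[j]);
  std::vector<std::vector<int>> acc(n_rungs, std::vector<int>(d, 0)),
      tri(n_rungs, std::vector<int>(d, 0));

  const int n_keep = n_iterations - warmup;
  NumericMatrix keep(n_keep, d);
  long n_acc_post = 0;
  std::vector<double> prop(d);

  for (int i = 1; i <= n_iterations; ++i) {
    for (int r = 0; r < n_rungs; ++r) {
      const double b = betas[r];
      for (int j = 0; j < d; ++j) {
        prop = TH[r];
        if (unif_rand() < 0.1)
          prop[j] = lo[j] + unif_rand() * (hi[j] - lo[j]);
        else
          prop[j] = TH[r][j] + norm_rand() * SC[r][j];
        double lp = target(prop);
        ++tri[r][j];
        double lr = (lp == R_NegInf) ? R_NegInf : b * (lp - LL[r]);
        if (std::log(unif_rand()) < lr) {
          TH[r] = prop;
          LL[r] = lp;
          ++acc[r][j];
          if (i > warmup && r == 0) ++n_acc_post;
        }
      }
    }
    // sweep swap attempts hot-to-cold so a mode found in the hottest rung
    // can reach the cold rung within one iteration
    for (int r = n_rungs - 2; r >= 0; --r) {
      double lsw = (betas[r] - betas[r + 1]) * (LL[r + 1] - LL[r]);
      if (std::log(unif_rand()) < lsw) {
        std::swap(TH[r], TH[r + 1]);
        std::swap(LL[r], LL[r + 1]);
      }
    }
    if (i <= warmup && i % 50 == 0) {
      for (int r = 0; r < n_rungs; ++r)
        for (int j = 0; j < d; ++j) {
          double rate = tri[r][j] > 0 ? (double)acc[r][j] / tri[r][j] : 0.0;
          double f = 2.0 * (rate - 0.3);
          if (f > 0.7) f = 0.7;
          if (f < -0.7) f = -0.7;
          SC[r][j] *= std::exp(f);
          acc[r][j] = 0;
          tri[r][j] = 0;
        }
    }
    if (i > warmup)
      for (int j = 0; j < d; ++j) keep(i - warmup - 1, j) = TH[0][j];
  }
  double acc_rate = (double)n_acc_post / ((double)n_keep * d);
  return List::create(_["draws"] = keep, _["acceptance"] = acc_rate);
}
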