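#include <Rcpp.h>
using namespace Rcpp;

// Single-site Gibbs sampler for the whole-genome regression
//   y = mu + Z beta + e,  e ~ N(0, I sigma2_e)
// variant 0 = BayesA   (per-marker variances, scaled-inv-chi2 prior)
// variant 1 = BayesB   (spike-and-slab, per-marker slab variances, pi fixed)
// variant 2 = BayesCpi (spike-and-slab, common slab variance, pi ~ Beta posterior)
// Uses R's RNG throughout so set.seed() makes chains reproducible.
// [[Rcpp::export]]
List bayes_alphabet_gibbs(NumericVector y, NumericMatrix Z, int variant,
                          int n_iter, int burn_in,
                          double pi_init, bool update_pi,
                          double nu_beta, double scale_beta,
                          double nu_e, double scale_e) {
  const int n = y.size();
  const int p = Z.ncol();
  if (Z.nrow() != n) stop("Z rows must match length(y).");
  if (n_iter <= burn_in || burn_in < 0) stop("Need n_iter > burn_in >= 0.");

  std::vector<double> zz(p);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    const double* z = &Z(0, j);
    for (int i = 0; i < n; ++i) s += z[i] * z[i];
    zz[j] = s;
  }

  std::vector<double> beta(p, 0.0), s2j(p, 0.0);
  const double prior_var = nu_beta * scale_beta / (nu_beta - 2.0);
  for (int j = 0; j < p; ++j) s2j[j] = prior_var;
  double s2b = prior_var;                 // common slab variance (BayesCpi)
  double mu = mean(y);
  double s2e = var(y) / 2.0;
  double pi = pi_init;                    // P(marker has a non-zero effect)
  std::vector<int> delta(p, variant == 0 ? 1 : 0);

  std::vector<double> e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;

  std::vector<double> beta_sum(p, 0.0), incl_sum(p, 0.0);
  double mu_sum = 0.0, s2e_sum = 0.0, pi_sum = 0.0;
  int kept = 0;

  for (int it = 0; it < n_iter; ++it) {
    // intercept
    double em = 0.0;
    for (int i = 0; i < n; ++i) em += e[i];
    em = em / n + mu;
    double mu_new = R::rnorm(em, std::sqrt(s2e / n));
    double shift = mu - mu_new;
    for (int i = 0; i < n; ++i) e[i] += shift;
    mu = mu_new;

    int k_in = 0;
    double ssb_in = 0.0;
    for (int j = 0; j < p; ++j) {
      if (zz[j] <= 0.0) continue;        // monomorphic after centering
      const double* z = &Z(0, j);
      const double old = beta[j];
      double r = 0.0;
      for (int i = 0; i < n; ++i) r += z[i] * e[i];
      r += zz[j] * old;                  // marker-excluded residual statistic

      double s2 = (variant == 2) ? s2b : s2j[j];
      bool in_model = true;
      if (variant != 0) {
        const double v = zz[j] * s2 + s2e;
        const double log_bf = -0.5 * std::log(v / s2e)
          + 0.5 * r * r * s2 / (s2e * v);
        const double p1 = 1.0 / (1.0 + (1.0 - pi) / pi * std::exp(-log_bf));
        in_model = (R::unif_rand() < p1);
      }

      double bnew = 0.0;
      if (in_model) {
        const double C = zz[j] + s2e / s2;
        bnew = R::rnorm(r / C, std::sqrt(s2e / C));
      }
      if (bnew != old) {
        const double d = bnew - old;
        for (int i = 0; i < n; ++i) e[i] -= z[i] * d;
      }
      beta[j] = bnew;
      delta[j] = in_model ? 1 : 0;
      if (in_model) { ++k_in; ssb_in += bnew * bnew; }

      if (variant == 0) {
        s2j[j] = (nu_beta * scale_beta + bnew * bnew) / R::rchisq(nu_beta + 1.0);
      } else if (variant == 1) {
        s2j[j] = in_model
          ? (nu_beta * scale_beta + bnew * bnew) / R::rchisq(nu_beta + 1.0)
          : nu_beta * scale_beta / R::rchisq(nu_beta);
      }
    }

    if (variant == 2) {
      s2b = (nu_beta * scale_beta + ssb_in) / R::rchisq(nu_beta + k_in);
      if (update_pi) pi = R::rbeta(1.0 + k_in, 1.0 + p - k_in);
    }

    double sse = 0.0;
    for (int i = 0; i < n; ++i) sse += e[i] * e[i];
    s2e = (sse + nu_e * scale_e) / R::rchisq(nu_e + n);

    if (it >= burn_in) {
      for (int j = 0; j < p; ++j) {
        beta_sum[j] += beta[j];
        incl_sum[j] += delta[j];
      }
      mu_sum += mu;
      s2e_sum += s2e;
      pi_sum += pi;
      ++kept;
    }
  }

  NumericVector beta_mean(p), incl(p);
  for (int j = 0; j < p; ++j) {
    beta_mean[j] = beta_sum[j] / kept;
    incl[j] = incl_sum[j] / kept;
  }
  return List::create(
    _["beta_mean"] = beta_mean,
    _["inclusion_prob"] = incl,
    _["mu_mean"] = mu_sum / kept,
    _["sigma2_e_mean"] = s2e_sum / kept,
    _["pi_mean"] = pi_sum / kept,
    _["kept_samples"] = kept);
}
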