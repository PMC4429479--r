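// Gibbs sampler for Bayesian hierarchical logistic regression with an
// area-level random intercept and (optionally) spike-and-slab mixture
// priors on a subset of design columns (stochastic search variable
// selection).  Bernoulli-logit likelihood is handled by Polya-Gamma
// data augmentation, so every conditional update is exact:
//   omega_i | .  ~ PG(1, eta_i)
//   gamma_j | .  ~ Bernoulli(full-conditional from the two normal densities)
//   beta    | .  ~ N((X'OX + D)^{-1} X'(kappa - O u), (X'OX + D)^{-1})
//   u_t     | .  ~ N(., .) per tract (conjugate)
//   sigma^2 | .  ~ inverse-gamma truncated to the uniform hyperprior support
// All randomness flows through R's RNG (seed with set.seed()).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

double rpg1(double z); // rpg.cpp

using namespace Rcpp;

// draw sigma from p(sigma | u) \propto sigma^{-T} exp(-S/(2 sigma^2))
// on (lo, hi], via the exact truncated gamma on the precision scale
static double draw_sigma(int T, double S, double lo, double hi) {
  double a = 0.5 * (T - 1.0);
  double b = std::max(0.5 * S, 1e-12); // rate
  double scale = 1.0 / b;
  double p_lo = R::pgamma(1.0 / (hi * hi), a, scale, 1, 0);
  double p_hi = (lo > 0.0) ? R::pgamma(1.0 / (lo * lo), a, scale, 1, 0) : 1.0;
  if (p_hi - p_lo < 1e-14) {
    // essentially all precision mass below 1/hi^2: sigma pinned at the bound
    return (p_lo > 0.5) ? hi : std::max(lo, 1e-8);
  }
  double u = p_lo + unif_rand() * (p_hi - p_lo);
  double x = R::qgamma(u, a, scale, 1, 0);
  return 1.0 / std::sqrt(std::max(x, 1e-300));
}

// [[Rcpp::export(name = ".pg_gibbs")]]
List pg_gibbs(const arma::mat& X, const arma::vec& y,
              const arma::ivec& tract, int n_tracts,
              const arma::vec& prior_prec, const arma::ivec& mix_idx,
              double spike_var, double slab_var, double incl_prob,
              double sigma_lo, double sigma_hi,
              int n_iter, int n_burn,
              const arma::vec& beta_init, double sigma_init) {
  const int n = X.n_rows, p = X.n_cols, m = mix_idx.n_elem;
  const bool has_re = n_tracts > 0;

  arma::vec beta = beta_init;
  arma::vec u(std::max(n_tracts, 1), arma::fill::zeros);
  arma::vec u_sub(n, arma::fill::zeros);
  double sigma = sigma_init;

  arma::vec kappa = y - 0.5;
  arma::vec omega(n), d = prior_prec, eta(n);
  arma::ivec gam(std::max(m, 1), arma::fill::ones);

  arma::mat beta_out(n_iter, p);
  arma::vec sigma_out(n_iter, arma::fill::value(NA_REAL));
  arma::imat gamma_out(n_iter, std::max(m, 1), arma::fill::zeros);
  arma::mat rb_out(n_iter, std::max(m, 1), arma::fill::zeros);
  arma::vec u_mean(std::max(n_tracts, 1), arma::fill::zeros);

  const double sd_slab = std::sqrt(slab_var), sd_spike = std::sqrt(spike_var);
  const double lprior_odds = std::log(incl_prob) - std::log1p(-incl_prob);
  int n_keep = 0;

  for (int t = 0; t < n_iter; ++t) {
    // omega | beta, u
    eta = X * beta + u_sub;
    for (int i = 0; i < n; ++i) omega[i] = rpg1(eta[i]);

    // gamma | beta  (mixture columns only)
    for (int j = 0; j < m; ++j) {
      double b = beta[mix_idx[j]];
      double lo = lprior_odds
        + R::dnorm(b, 0.0, sd_slab, 1) - R::dnorm(b, 0.0, sd_spike, 1);
      double p1 = 1.0 / (1.0 + std::exp(-lo));
      gam[j] = (unif_rand() < p1) ? 1 : 0;
      rb_out(t, j) = p1;
      gamma_out(t, j) = gam[j];
      d[mix_idx[j]] = gam[j] ? 1.0 / slab_var : 1.0 / spike_var;
    }

    // beta | omega, u, gamma
    arma::mat M = X.t() * (X.each_col() % omega);
    M.diag() += d;
    arma::vec rhs = X.t() * (kappa - omega % u_sub);
    arma::mat L = arma::chol(M, "lower");
    arma::vec mu = arma::solve(arma::trimatu(L.t()),
                               arma::solve(arma::trimatl(L), rhs));
    arma::vec z(p);
    for (int j = 0; j < p; ++j) z[j] = norm_rand();
    beta = mu + arma::solve(arma::trimatu(L.t()), z);

    if (has_re) {
      // u | omega, beta, sigma  (scalar conjugate updates)
      arma::vec eta_fix = X * beta;
      arma::vec sw(n_tracts, arma::fill::zeros), sr(n_tracts, arma::fill::zeros);
      for (int i = 0; i < n; ++i) {
        sw[tract[i]] += omega[i];
        sr[tract[i]] += kappa[i] - omega[i] * eta_fix[i];
      }
      double s2inv = 1.0 / std::max(sigma * sigma, 1e-12);
      for (int g = 0; g < n_tracts; ++g) {
        double prec = sw[g] + s2inv;
        u[g] = sr[g] / prec + norm_rand() / std::sqrt(prec);
      }
      for (int i = 0; i < n; ++i) u_sub[i] = u[tract[i]];

      // sigma | u
      sigma = draw_sigma(n_tracts, arma::dot(u, u), sigma_lo, sigma_hi);
      sigma_out[t] = sigma;
    }

    beta_out.row(t) = beta.t();
    if (t >= n_burn) { u_mean += u; ++n_keep; }
  }
  if (n_keep > 0) u_mean /= n_keep;

  return List::create(
    _["beta"] = beta_out, _["sigma"] = sigma_out,
    _["gamma"] = gamma_out, _["rb_prob"] = rb_out,
    _["u_mean"] = u_mean, _["n_keep"] = n_keep);
}
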