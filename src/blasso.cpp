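// Park-Casella Bayesian Lasso Gibbs sampler, single-site scan variant.
//
// Hierarchy: beta_j | tau2_j, sigma2 ~ N(0, sigma2 * tau2_j),
// tau2_j ~ Exp(lambda2 / 2), lambda2 ~ Gamma(r, delta), flat mu,
// scale-invariant prior 1/sigma2.  Columns of X are centered by the
// caller; beta stays on the original dosage scale.  Each sweep updates
// mu, every beta_j in turn with residual updating (O(n) per marker),
// the latent tau2_j, sigma2 and lambda2.  R's RNG is used throughout so
// set.seed() in R makes draws reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Michael-Schucany-Haas inverse-Gaussian sampler.
static double rinvgauss1(double mu, double lambda) {
  const double nu = R::norm_rand();
  const double y = nu * nu;
  double x = mu + mu * mu * y / (2.0 * lambda) -
    mu / (2.0 * lambda) *
      std::sqrt(4.0 * mu * lambda * y + mu * mu * y * y);
  if (x <= 0.0 || !std::isfinite(x)) x = mu * 1e-10;
  if (R::unif_rand() <= mu / (mu + x)) return x;
  return mu * mu / x;
}

// [[Rcpp::export(name = ".blasso_scan")]]
List blasso_scan(const arma::mat& X, const arma::vec& y,
                 int n_iter, int burn_in, int thin,
                 double r_hyp, double delta_hyp) {
  const arma::uword n = X.n_rows, g = X.n_cols;
  const arma::vec xtx = arma::sum(arma::square(X), 0).t();

  double mu = arma::mean(y);
  double sigma2 = arma::var(y);
  if (!(sigma2 > 0)) sigma2 = 1.0;
  double lambda2 = 1.0;
  arma::vec beta(g, arma::fill::zeros);
  arma::vec invtau2(g, arma::fill::ones);
  arma::vec e = y - mu;  // residual y - mu - X*beta (beta = 0)

  const int n_keep = (n_iter - burn_in) / thin;
  arma::mat beta_draws(n_keep, g);
  arma::vec mu_draws(n_keep), sigma2_draws(n_keep), lambda2_draws(n_keep);

  int kept = 0;
  for (int iter = 1; iter <= n_iter; ++iter) {
    // mu | . ~ N(mean(y - X beta), sigma2 / n)
    const double m = arma::mean(e) + mu;
    const double mu_new = m + R::norm_rand() * std::sqrt(sigma2 / n);
    e += mu - mu_new;
    mu = mu_new;

    // beta_j | . single-site scan with residual updating
    double* ep = e.memptr();
    for (arma::uword j = 0; j < g; ++j) {
      const double* xj = X.colptr(j);
      const double bj = beta(j);
      double dot = 0.0;
      for (arma::uword i = 0; i < n; ++i) dot += xj[i] * ep[i];
      const double rj = dot + xtx(j) * bj;
      const double prec = xtx(j) + invtau2(j);
      const double mean_j = rj / prec;
      const double bnew = mean_j + R::norm_rand() * std::sqrt(sigma2 / prec);
      const double delta = bj - bnew;
      if (delta != 0.0)
        for (arma::uword i = 0; i < n; ++i) ep[i] += xj[i] * delta;
      beta(j) = bnew;
    }

    // 1/tau2_j | . ~ InvGauss(sqrt(lambda2 sigma2 / beta_j^2), lambda2)
    for (arma::uword j = 0; j < g; ++j) {
      const double b2 = std::max(beta(j) * beta(j), 1e-20);
      double mu_ig = std::sqrt(lambda2 * sigma2 / b2);
      if (mu_ig > 1e10) mu_ig = 1e10;
      invtau2(j) = rinvgauss1(mu_ig, lambda2);
    }

    // sigma2 | . ~ InvGamma((n-1)/2 + g/2, e'e/2 + sum(b^2 invtau2)/2)
    const double shape_s = 0.5 * (n - 1.0) + 0.5 * g;
    const double rate_s = 0.5 * arma::dot(e, e) +
      0.5 * arma::dot(arma::square(beta), invtau2);
    sigma2 = 1.0 / R::rgamma(shape_s, 1.0 / rate_s);

    // lambda2 | . ~ Gamma(r + g, delta + sum(tau2)/2)
    const double rate_l = delta_hyp + 0.5 * arma::sum(1.0 / invtau2);
    lambda2 = R::rgamma(r_hyp + g, 1.0 / rate_l);

    if (iter > burn_in && (iter - burn_in) % thin == 0 && kept < n_keep) {
      beta_draws.row(kept) = beta.t();
      mu_draws(kept) = mu;
      sigma2_draws(kept) = sigma2;
      lambda2_draws(kept) = lambda2;
      ++kept;
    }
  }

  return List::create(_["beta"] = beta_draws,
                      _["mu"] = mu_draws,
                      _["sigma2"] = sigma2_draws,
                      _["lambda2"] = lambda2_draws);
}
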