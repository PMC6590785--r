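// Per-group ordinary least squares with explicit detection of columns
// lying in the span of preceding columns.  Groups are small (tens of
// markers) and fitted tens of thousands of times per tournament, so the
// fit works on the Gram matrix of the design: an incremental Cholesky
// factorisation screens columns left to right, and a column whose
// out-of-span residual norm falls below tol * ||D||_F (Frobenius norm
// of the design, a tight proxy for its largest singular value at these
// tolerances) is flagged non-estimable and excluded.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

List ols_group_impl(const arma::mat& X, const arma::vec& y, double tol);

// [[Rcpp::export(name = ".ols_group")]]
List ols_group(const arma::mat& X, const arma::vec& y, double tol) {
  return ols_group_impl(X, y, tol);
}

// One call per tournament stage: fits every group against the shared
// design matrix, avoiding per-group copies through R.  Results are
// identical to calling .ols_group on each column subset.
// [[Rcpp::export(name = ".ols_batch")]]
List ols_batch(const arma::mat& X, const arma::vec& y, List groups,
               double tol) {
  const int K = groups.size();
  List out(K);
  for (int k = 0; k < K; ++k) {
    IntegerVector idx = groups[k];  // 1-based column indices
    arma::uvec cols(idx.size());
    for (int j = 0; j < idx.size(); ++j)
      cols(j) = static_cast<arma::uword>(idx[j] - 1);
    out[k] = ols_group_impl(X.cols(cols), y, tol);
  }
  return out;
}

List ols_group_impl(const arma::mat& X, const arma::vec& y, double tol) {
  const arma::uword n = X.n_rows, g = X.n_cols;
  const arma::uword m = g + 1;  // intercept + markers

  // Gram matrix of D = [1, X] without materialising D
  arma::mat G(m, m);
  G(0, 0) = static_cast<double>(n);
  const arma::rowvec cs = arma::sum(X, 0);
  G(0, arma::span(1, g)) = cs;
  G(arma::span(1, g), 0) = cs.t();
  G.submat(1, 1, g, g) = X.t() * X;

  arma::vec Dty(m);
  Dty(0) = arma::accu(y);
  Dty.subvec(1, g) = X.t() * y;

  const double frob = std::sqrt(arma::trace(G));
  const double thresh = tol * frob;

  // incremental Cholesky with column rejection
  arma::mat L(m, m, arma::fill::zeros);  // lower triangular, retained cols
  arma::uvec keep_idx(m);
  arma::uword r = 0;
  for (arma::uword j = 0; j < m; ++j) {
    arma::vec w(r);
    for (arma::uword k = 0; k < r; ++k) {
      double s = G(keep_idx(k), j);
      for (arma::uword t = 0; t < k; ++t) s -= L(k, t) * w(t);
      w(k) = s / L(k, k);
    }
    double d2 = G(j, j) - arma::dot(w, w);
    const double d = std::sqrt(std::max(d2, 0.0));
    if (d > thresh) {
      for (arma::uword k = 0; k < r; ++k) L(r, k) = w(k);
      L(r, r) = d;
      keep_idx(r) = j;
      ++r;
    }
  }

  arma::mat Lr = L.submat(0, 0, r - 1, r - 1);
  arma::uvec kept = keep_idx.head(r);
  arma::vec rhs(r);
  for (arma::uword k = 0; k < r; ++k) rhs(k) = Dty(kept(k));
  arma::vec b = arma::solve(arma::trimatu(Lr.t()),
                            arma::solve(arma::trimatl(Lr), rhs));

  const double df = static_cast<double>(n) - static_cast<double>(r);

  NumericVector estimate(g, NA_REAL), tval(g, NA_REAL), pval(g, NA_REAL);
  LogicalVector estimable(g);
  double sigma2 = NA_REAL;
  if (df > 0) {
    double rss = arma::dot(y, y) - arma::dot(b, rhs);
    if (rss < 0) rss = 0;
    sigma2 = rss / df;
    // diag of (D_kept' D_kept)^{-1} from the inverse Cholesky factor
    arma::mat Linv = arma::inv(arma::trimatl(Lr));
    const arma::vec dinv = arma::sum(arma::square(Linv), 0).t();
    for (arma::uword k = 0; k < r; ++k) {
      const arma::uword j = kept(k);
      if (j == 0) continue;  // intercept
      estimate[j - 1] = b(k);
      estimable[j - 1] = true;
      const double se = std::sqrt(sigma2 * dinv(k));
      if (se > 0) {
        const double t = b(k) / se;
        tval[j - 1] = t;
        pval[j - 1] = 2.0 * R::pt(-std::fabs(t), df, 1, 0);
      } else {
        tval[j - 1] = 0.0;
        pval[j - 1] = 1.0;
      }
    }
  } else {
    // saturated fit: coefficients exist but no error degrees of freedom
    for (arma::uword k = 0; k < r; ++k) {
      const arma::uword j = kept(k);
      if (j == 0) continue;
      estimate[j - 1] = b(k);
      estimable[j - 1] = true;
      pval[j - 1] = 1.0;
    }
  }

  return List::create(_["estimate"] = estimate,
                      _["t"] = tval,
                      _["p_value"] = pval,
                      _["estimable"] = estimable,
                      _["df"] = df,
                      _["sigma2"] = sigma2);
}
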