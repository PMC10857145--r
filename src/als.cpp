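// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Alternating ridge regression for R ~ mu + U M^T on observed entries.
// lam is an absolute ridge penalty per latent vector (not scaled by the
// number of observations), which keeps lightly-rated users from being
// over-shrunk relative to heavily-rated ones.
// [[Rcpp::export]]
List als_ridge(arma::mat U, arma::mat M,
               IntegerVector ui, IntegerVector mi, NumericVector y,
               int iters, double lam) {
  int k = U.n_cols;
  int n_obs = y.size();
  int n_u = U.n_rows, n_m = M.n_rows;
  arma::mat eye = lam * arma::eye(k, k);

  std::vector<std::vector<int>> by_u(n_u), by_m(n_m);
  for (int t = 0; t < n_obs; ++t) {
    by_u[ui[t]].push_back(t);
    by_m[mi[t]].push_back(t);
  }

  for (int it = 0; it < iters; ++it) {
    for (int u = 0; u < n_u; ++u) {
      const std::vector<int>& idx = by_u[u];
      if (idx.empty()) { U.row(u).zeros(); continue; }
      arma::mat X(idx.size(), k);
      arma::vec b(idx.size());
      for (size_t j = 0; j < idx.size(); ++j) {
        X.row(j) = M.row(mi[idx[j]]);
        b(j) = y[idx[j]];
      }
      U.row(u) = arma::solve(X.t() * X + eye, X.t() * b,
                             arma::solve_opts::likely_sympd).t();
    }
    for (int m = 0; m < n_m; ++m) {
      const std::vector<int>& idx = by_m[m];
      if (idx.empty()) { M.row(m).zeros(); continue; }
      arma::mat X(idx.size(), k);
      arma::vec b(idx.size());
      for (size_t j = 0; j < idx.size(); ++j) {
        X.row(j) = U.row(ui[idx[j]]);
        b(j) = y[idx[j]];
      }
      M.row(m) = arma::solve(X.t() * X + eye, X.t() * b,
                             arma::solve_opts::likely_sympd).t();
    }
  }
  return List::create(_["U"] = U, _["M"] = M);
}
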