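#include <Rcpp.h>
using namespace Rcpp;

// Stochastic gradient descent epochs for bias-augmented matrix
// factorization on observed ratings. Operates in place on copies and
// returns the updated parameters plus the per-epoch RMSE trace.
//
// ui, mi: 0-based user / meal indices per observed rating
// order: visiting order per epoch, one column per epoch (0-based)
// [[Rcpp::export]]
List funk_svd_sgd(NumericMatrix U, NumericMatrix M,
                  NumericVector bu, NumericVector bm, double mu,
                  IntegerVector ui, IntegerVector mi, NumericVector r,
                  IntegerMatrix order, double lr0, double reg,
                  double lr_decay) {
  int k = U.ncol();
  int n_obs = r.size();
  int epochs = order.ncol();
  NumericVector rmse(epochs);

  for (int e = 0; e < epochs; ++e) {
    double lr = lr0 / (1.0 + lr_decay * e);
    double sse = 0.0;
    for (int t = 0; t < n_obs; ++t) {
      int idx = order(t, e);
      int u = ui[idx];
      int m = mi[idx];
      double pred = mu + bu[u] + bm[m];
      for (int f = 0; f < k; ++f) pred += U(u, f) * M(m, f);
      double err = r[idx] - pred;
      sse += err * err;
      bu[u] += lr * (err - reg * bu[u]);
      bm[m] += lr * (err - reg * bm[m]);
      for (int f = 0; f < k; ++f) {
        double uf = U(u, f);
        double mf = M(m, f);
        U(u, f) += lr * (err * mf - reg * uf);
        M(m, f) += lr * (err * uf - reg * mf);
      }
    }
    rmse[e] = std::sqrt(sse / n_obs);
  }
  return List::create(_["U"] = U, _["M"] = M, _["bu"] = bu, _["bm"] = bm,
                      _["rmse"] = rmse);
}
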