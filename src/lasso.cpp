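#include <Rcpp.h>
using namespace Rcpp;

static inline double soft(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// Coordinate descent for min_w ||yc - Xc w||^2 + lambda ||w||_1 on the
// Gram scale: G = Xc'Xc (p x p), cty = Xc'yc (p). Solves the whole
// descending lambda path with warm starts. Stationarity condition per
// coordinate: w_j = soft(cty_j - sum_{k != j} G_jk w_k, lambda/2) / G_jj.
// [[Rcpp::export]]
NumericMatrix lasso_cd_gram(NumericMatrix G, NumericVector cty,
                            NumericVector lambda, double tol, int max_sweeps) {
  const int p = G.ncol();
  const int nl = lambda.size();
  NumericMatrix W(p, nl);
  std::vector<double> w(p, 0.0);
  // q_j = sum_k G_jk w_k, maintained incrementally
  std::vector<double> q(p, 0.0);
  for (int l = 0; l < nl; ++l) {
    const double thr = lambda[l] / 2.0;
    for (int sweep = 0; sweep < max_sweeps; ++sweep) {
      double maxdel = 0.0;
      for (int j = 0; j < p; ++j) {
        const double gjj = G(j, j);
        if (gjj <= 0.0) { w[j] = 0.0; continue; }
        const double z = cty[j] - q[j] + gjj * w[j];
        const double wj = soft(z, thr) / gjj;
        const double del = wj - w[j];
        if (del != 0.0) {
          for (int k = 0; k < p; ++k) q[k] += G(k, j) * del;
          w[j] = wj;
          double ad = std::fabs(del);
          if (ad > maxdel) maxdel = ad;
        }
      }
      if (maxdel < tol) break;
    }
    for (int j = 0; j < p; ++j) W(j, l) = w[j];
  }
  return W;
}
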