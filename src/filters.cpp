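#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter applied down each column of X.
// b, a are transfer-function coefficients with a[0] == 1.
// [[Rcpp::export]]
NumericMatrix iir_filter_mat(NumericVector b, NumericVector a, NumericMatrix X) {
  const int n = X.nrow(), nc = X.ncol();
  const int nb = b.size(), na = a.size();
  const int nz = std::max(nb, na) - 1;
  NumericMatrix Y(n, nc);
  std::vector<double> bb(nz + 1, 0.0), aa(nz + 1, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  std::vector<double> z(nz);
  for (int c = 0; c < nc; ++c) {
    std::fill(z.begin(), z.end(), 0.0);
    for (int t = 0; t < n; ++t) {
      double x = X(t, c);
      double y = bb[0] * x + z[0];
      for (int k = 0; k < nz - 1; ++k)
        z[k] = bb[k + 1] * x + z[k + 1] - aa[k + 1] * y;
      if (nz > 0)
        z[nz - 1] = bb[nz] * x - aa[nz] * y;
      Y(t, c) = y;
    }
  }
  return Y;
}

// Zero-phase filtering down each column: odd (reflected) edge padding of
// `pad` rows, forward pass, backward pass, padding stripped.
// [[Rcpp::export]]
NumericMatrix filtfilt_mat_cpp(NumericVector b, NumericVector a,
                               NumericMatrix X, int pad) {
  const int n = X.nrow(), nc = X.ncol();
  if (pad > n - 1) pad = n - 1;
  const int m = n + 2 * pad;
  const int nb = b.size(), na = a.size();
  const int nz = std::max(nb, na) - 1;
  std::vector<double> bb(nz + 1, 0.0), aa(nz + 1, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  NumericMatrix Y(n, nc);
  std::vector<double> buf(m), z(nz);
  for (int c = 0; c < nc; ++c) {
    // odd reflection about the end points
    for (int t = 0; t < pad; ++t)
      buf[t] = 2.0 * X(0, c) - X(pad - t, c);
    for (int t = 0; t < n; ++t) buf[pad + t] = X(t, c);
    for (int t = 0; t < pad; ++t)
      buf[pad + n + t] = 2.0 * X(n - 1, c) - X(n - 2 - t, c);
    for (int dir = 0; dir < 2; ++dir) {
      std::fill(z.begin(), z.end(), 0.0);
      if (dir == 0) {
        for (int t = 0; t < m; ++t) {
          double x = buf[t];
          double y = bb[0] * x + z[0];
          for (int k = 0; k < nz - 1; ++k)
            z[k] = bb[k + 1] * x + z[k + 1] - aa[k + 1] * y;
          if (nz > 0) z[nz - 1] = bb[nz] * x - aa[nz] * y;
          buf[t] = y;
        }
      } else {
        for (int t = m - 1; t >= 0; --t) {
          double x = buf[t];
          double y = bb[0] * x + z[0];
          for (int k = 0; k < nz - 1; ++k)
            z[k] = bb[k + 1] * x + z[k + 1] - aa[k + 1] * y;
          if (nz > 0) z[nz - 1] = bb[nz] * x - aa[nz] * y;
          buf[t] = y;
        }
      }
    }
    for (int t = 0; t < n; ++t) Y(t, c) = buf[pad + t];
  }
  return Y;
}

// Sum of squares over consecutive non-overlapping windows of `win` rows,
// per column: returns floor(nrow/win) x ncol matrix of window powers.
// [[Rcpp::export]]
NumericMatrix window_sumsq(NumericMatrix X, int win) {
  const int n = X.nrow(), nc = X.ncol();
  const int nw = n / win;
  NumericMatrix P(nw, nc);
  for (int c = 0; c < nc; ++c) {
    for (int w = 0; w < nw; ++w) {
      double s = 0.0;
      const int off = w * win;
      for (int t = 0; t < win; ++t) {
        double v = X(off + t, c);
        s += v * v;
      }
      P(w, c) = s;
    }
  }
  return P;
}
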