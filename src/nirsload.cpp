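#include <Rcpp.h>
using namespace Rcpp;

// Direct-form-II-transposed IIR filter with initial state, matching the
// classic lfilter contract: a[0] must be 1 (caller normalises), b and a
// padded to equal length n, zi of length n - 1.
// [[Rcpp::export]]
List cpp_lfilter(NumericVector b, NumericVector a, NumericVector x,
                 NumericVector zi) {
  int n = b.size();
  if (a.size() != n) stop("b and a must have equal length");
  if (zi.size() != n - 1) stop("zi must have length length(b) - 1");
  int m = x.size();
  NumericVector y(m);
  std::vector<double> z(zi.begin(), zi.end());
  for (int t = 0; t < m; ++t) {
    double xt = x[t];
    double yt = b[0] * xt + (n > 1 ? z[0] : 0.0);
    for (int i = 0; i < n - 2; ++i)
      z[i] = b[i + 1] * xt + z[i + 1] - a[i + 1] * yt;
    if (n > 1) z[n - 2] = b[n - 1] * xt - a[n - 1] * yt;
    y[t] = yt;
  }
  return List::create(_["y"] = y, _["zf"] = NumericVector(z.begin(), z.end()));
}

static void lfilter_inplace(const std::vector<double>& b,
                            const std::vector<double>& a,
                            std::vector<double>& x,
                            const std::vector<double>& zi0, double scale) {
  int n = b.size();
  std::vector<double> z(n - 1);
  for (int i = 0; i < n - 1; ++i) z[i] = zi0[i] * scale;
  int m = x.size();
  for (int t = 0; t < m; ++t) {
    double xt = x[t];
    double yt = b[0] * xt + (n > 1 ? z[0] : 0.0);
    for (int i = 0; i < n - 2; ++i)
      z[i] = b[i + 1] * xt + z[i + 1] - a[i + 1] * yt;
    if (n > 1) z[n - 2] = b[n - 1] * xt - a[n - 1] * yt;
    x[t] = yt;
  }
}

// Zero-phase forward-backward filtering of each column of X with odd end
// padding and steady-state initial conditions (zi from lfilter_zi).
// [[Rcpp::export]]
NumericMatrix cpp_filtfilt_mat(NumericVector b, NumericVector a,
                               NumericMatrix X, NumericVector zi,
                               int padlen) {
  int n = b.size();
  if (a.size() != n || zi.size() != n - 1) stop("coefficient size mismatch");
  int nr = X.nrow(), nc = X.ncol();
  if (nr <= padlen) stop("series too short for the requested padding");
  std::vector<double> bb(b.begin(), b.end()), aa(a.begin(), a.end()),
      zz(zi.begin(), zi.end());
  NumericMatrix out(nr, nc);
  int ext_n = nr + 2 * padlen;
  std::vector<double> ext(ext_n);
  for (int c = 0; c < nc; ++c) {
    for (int i = 0; i < padlen; ++i)
      ext[i] = 2.0 * X(0, c) - X(padlen - i, c);
    for (int i = 0; i < nr; ++i) ext[padlen + i] = X(i, c);
    for (int i = 0; i < padlen; ++i)
      ext[padlen + nr + i] = 2.0 * X(nr - 1, c) - X(nr - 2 - i, c);
    lfilter_inplace(bb, aa, ext, zz, ext[0]);
    std::reverse(ext.begin(), ext.end());
    lfilter_inplace(bb, aa, ext, zz, ext[0]);
    std::reverse(ext.begin(), ext.end());
    for (int i = 0; i < nr; ++i) out(i, c) = ext[padlen + i];
  }
  return out;
}

// L2-regularised L1-loss linear SVM, solved in the dual by coordinate
// descent (Hsieh et al. 2008). X must already carry a bias column if an
// intercept is wanted; y in {-1, +1}. Deterministic: fixed visiting order.
// [[Rcpp::export]]
NumericVector cpp_svm_train(NumericMatrix X, NumericVector y, double C,
                            int max_passes, double tol) {
  int n = X.nrow(), d = X.ncol();
  if (y.size() != n) stop("label length mismatch");
  std::vector<double> w(d, 0.0), alpha(n, 0.0), qii(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < d; ++j) s += X(i, j) * X(i, j);
    qii[i] = s;
  }
  for (int pass = 0; pass < max_passes; ++pass) {
    double max_viol = 0.0;
    for (int i = 0; i < n; ++i) {
      if (qii[i] <= 0.0) continue;
      double wx = 0.0;
      for (int j = 0; j < d; ++j) wx += w[j] * X(i, j);
      double G = y[i] * wx - 1.0;
      double PG = G;
      if (alpha[i] <= 0.0) PG = std::min(G, 0.0);
      else if (alpha[i] >= C) PG = std::max(G, 0.0);
      if (std::fabs(PG) > max_viol) max_viol = std::fabs(PG);
      if (std::fabs(PG) > 1e-12) {
        double a_new = std::min(std::max(alpha[i] - G / qii[i], 0.0), C);
        double delta = (a_new - alpha[i]) * y[i];
        if (delta != 0.0) {
          for (int j = 0; j < d; ++j) w[j] += delta * X(i, j);
          alpha[i] = a_new;
        }
      }
    }
    if (max_viol < tol) break;
  }
  return NumericVector(w.begin(), w.end());
}
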