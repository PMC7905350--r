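#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Direct form II transposed IIR filter. Coefficients are normalized by a[0];
// zi supplies the initial delay-line state (length max(na, nb) - 1), used by
// the zero-phase wrapper to suppress start-up transients.
// [[Rcpp::export]]
NumericVector iir_filter_cpp(NumericVector b, NumericVector a, NumericVector x,
                             NumericVector zi) {
  int nb = b.size(), na = a.size();
  int n = std::max(nb, na);
  std::vector<double> bb(n, 0.0), aa(n, 0.0);
  for (int i = 0; i < nb; i++) bb[i] = b[i];
  for (int i = 0; i < na; i++) aa[i] = a[i];
  double a0 = aa[0];
  if (a0 == 0.0) stop("a[1] must be non-zero");
  for (int i = 0; i < n; i++) { bb[i] /= a0; aa[i] /= a0; }

  int nz = n - 1;
  std::vector<double> z(nz > 0 ? nz : 1, 0.0);
  if (zi.size() > 0) {
    if (zi.size() != nz) stop("zi has wrong length");
    for (int i = 0; i < nz; i++) z[i] = zi[i];
  }

  int m = x.size();
  NumericVector y(m);
  if (nz == 0) {
    for (int t = 0; t < m; t++) y[t] = bb[0] * x[t];
    return y;
  }
  for (int t = 0; t < m; t++) {
    double xt = x[t];
    double yt = bb[0] * xt + z[0];
    for (int i = 1; i < nz; i++) {
      z[i - 1] = bb[i] * xt + z[i] - aa[i] * yt;
    }
    z[nz - 1] = bb[nz] * xt - aa[nz] * yt;
    y[t] = yt;
  }
  return y;
}
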