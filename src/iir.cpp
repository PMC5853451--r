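#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Direct-form II transposed IIR filter with explicit carried state.
// NaN samples propagate to the output and reset the internal state, so no
// transient leaks across a detached-electrode gap.
// [[Rcpp::export]]
List iir_df2t(NumericVector b, NumericVector a, NumericVector x,
              Nullable<NumericVector> zi = R_NilValue) {
  int nb = b.size(), na = a.size();
  int nz = std::max(na, nb) - 1;
  std::vector<double> bb(nz + 1, 0.0), aa(nz + 1, 0.0);
  double a0 = a[0];
  if (a0 == 0.0) stop("a[1] must be non-zero");
  for (int i = 0; i < nb; i++) bb[i] = b[i] / a0;
  for (int i = 0; i < na; i++) aa[i] = a[i] / a0;
  std::vector<double> z(nz, 0.0);
  if (zi.isNotNull()) {
    NumericVector z0(zi);
    if ((int)z0.size() != nz) stop("state has wrong length");
    for (int i = 0; i < nz; i++) z[i] = z0[i];
  }
  int n = x.size();
  NumericVector y(n);
  for (int t = 0; t < n; t++) {
    double xt = x[t];
    if (!std::isfinite(xt)) {
      y[t] = NA_REAL;
      std::fill(z.begin(), z.end(), 0.0);
      continue;
    }
    double yt = bb[0] * xt + z[0];
    for (int i = 0; i < nz - 1; i++) z[i] = bb[i + 1] * xt - aa[i + 1] * yt + z[i + 1];
    if (nz > 0) z[nz - 1] = bb[nz] * xt - aa[nz] * yt;
    y[t] = yt;
  }
  return List::create(_["y"] = y, _["zf"] = NumericVector(z.begin(), z.end()));
}
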