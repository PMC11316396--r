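#include <Rcpp.h>
using namespace Rcpp;

// Direct-form-II transposed IIR filter. Single pass; zero initial state.
// Used by the R-level zero-phase (forward-backward) Butterworth wrapper and
// by the pink-noise generator. Kept in C++ because clips are several million
// samples long (10 s at 256 kHz).
// [[Rcpp::export(name = ".iir_filter")]]
NumericVector iir_filter(NumericVector b, NumericVector a, NumericVector x) {
  int nb = b.size(), na = a.size(), n = x.size();
  if (na < 1 || a[0] == 0.0) stop("invalid denominator coefficients");
  int nw = std::max(nb, na) - 1;
  double a0 = a[0];
  std::vector<double> bn(nw + 1, 0.0), an(nw + 1, 0.0), w(nw, 0.0);
  for (int k = 0; k < nb; ++k) bn[k] = b[k] / a0;
  for (int k = 0; k < na; ++k) an[k] = a[k] / a0;
  NumericVector y(n);
  const double *xp = x.begin();
  double *yp = y.begin();
  for (int i = 0; i < n; ++i) {
    double xi = xp[i];
    double yn = bn[0] * xi + (nw > 0 ? w[0] : 0.0);
    for (int k = 0; k < nw - 1; ++k) {
      w[k] = w[k + 1] + bn[k + 1] * xi - an[k + 1] * yn;
    }
    if (nw > 0) w[nw - 1] = bn[nw] * xi - an[nw] * yn;
    yp[i] = yn;
  }
  return y;
}
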