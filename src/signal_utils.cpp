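// Compiled signal helpers: zero-phase IIR filtering for the synthetic EMG
// carrier, a sparse inverse DFT for the spectral Hampel correction, and
// per-channel standardization.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

// Direct-form II transposed IIR filter, zero initial state.
void iir_filter(const std::vector<double>& b, const std::vector<double>& a,
                const double* x, double* y, int n) {
  const int nb = b.size(), na = a.size();
  const int nz = std::max(nb, na) - 1;
  std::vector<double> z(nz, 0.0);
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = b[0] * xi + (nz > 0 ? z[0] : 0.0);
    for (int j = 0; j < nz; ++j) {
      double zn = (j + 1 < nz) ? z[j + 1] : 0.0;
      double bj = (j + 1 < nb) ? b[j + 1] : 0.0;
      double aj = (j + 1 < na) ? a[j + 1] : 0.0;
      z[j] = bj * xi + zn - aj * yi;
    }
    y[i] = yi;
  }
}

}  // namespace

// Forward-backward (zero-phase) IIR filtering with zero initial conditions.
// [[Rcpp::export]]
NumericVector cpp_filtfilt(NumericVector b, NumericVector a, NumericVector x) {
  const int n = x.size();
  std::vector<double> bb(b.begin(), b.end()), aa(a.begin(), a.end());
  const double a0 = aa[0];
  for (size_t i = 0; i < bb.size(); ++i) bb[i] /= a0;
  for (size_t i = 0; i < aa.size(); ++i) aa[i] /= a0;
  std::vector<double> y1(n), y2(n);
  iir_filter(bb, aa, REAL(x), y1.data(), n);
  std::reverse(y1.begin(), y1.end());
  iir_filter(bb, aa, y1.data(), y2.data(), n);
  std::reverse(y2.begin(), y2.end());
  return NumericVector(y2.begin(), y2.end());
}

// Per-channel z-scoring; channels with non-positive or non-finite sd map to 0.
// [[Rcpp::export]]
NumericMatrix cpp_standardize(NumericMatrix X, NumericVector mu,
                              NumericVector sd) {
  const int n = X.nrow(), C = X.ncol();
  NumericMatrix out(n, C);
  for (int c = 0; c < C; ++c) {
    const double m = mu[c], s = sd[c];
    if (!std::isfinite(s) || s <= 0) {
      for (int i = 0; i < n; ++i) out(i, c) = 0.0;
    } else {
      for (int i = 0; i < n; ++i) out(i, c) = (X(i, c) - m) / s;
    }
  }
  return out;
}
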