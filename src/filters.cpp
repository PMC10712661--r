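#include <Rcpp.h>
using namespace Rcpp;

// Cascade of biquad sections in direct-form II transposed.
// sos: nsec x 6 matrix, rows (b0, b1, b2, a0, a1, a2) with a0 == 1.
// zi: nsec x 2 initial state (modified copy is not returned; states are
// internal to one call). Used by the zero-phase wrapper on the R side.
// [[Rcpp::export]]
NumericVector sosfilt_cpp(NumericMatrix sos, NumericVector x, NumericMatrix zi) {
  const int ns = sos.nrow();
  const int n = x.size();
  NumericVector y = clone(x);
  NumericMatrix z = clone(zi);
  for (int s = 0; s < ns; ++s) {
    const double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
    const double a1 = sos(s, 4), a2 = sos(s, 5);
    double z1 = z(s, 0), z2 = z(s, 1);
    for (int i = 0; i < n; ++i) {
      const double xi = y[i];
      const double yi = b0 * xi + z1;
      z1 = b1 * xi - a1 * yi + z2;
      z2 = b2 * xi - a2 * yi;
      y[i] = yi;
    }
  }
  return y;
}

// Moving-window sum (for Pan-Tompkins integration); window w samples,
// causal, partial windows at the start averaged over the samples seen.
// [[Rcpp::export]]
NumericVector movmean_causal_cpp(NumericVector x, int w) {
  const int n = x.size();
  NumericVector y(n);
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    acc += x[i];
    if (i >= w) acc -= x[i - w];
    y[i] = acc / std::min(i + 1, w);
  }
  return y;
}

// Running median with centered window of half-width h samples, truncated at
// the edges (no reflection). O(n * w log w) via per-window nth_element; fine
// for the 5 Hz electrodermal traces this serves.
// [[Rcpp::export]]
NumericVector runmed_truncated_cpp(NumericVector x, int h) {
  const int n = x.size();
  NumericVector y(n);
  std::vector<double> buf;
  buf.reserve(2 * h + 1);
  for (int i = 0; i < n; ++i) {
    const int lo = std::max(0, i - h);
    const int hi = std::min(n - 1, i + h);
    buf.assign(x.begin() + lo, x.begin() + hi + 1);
    const int m = buf.size();
    std::nth_element(buf.begin(), buf.begin() + m / 2, buf.end());
    double med = buf[m / 2];
    if (m % 2 == 0) {
      std::nth_element(buf.begin(), buf.begin() + m / 2 - 1, buf.begin() + m / 2);
      med = 0.5 * (med + buf[m / 2 - 1]);
    }
    y[i] = med;
  }
  return y;
}
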