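#include <Rcpp.h>
using namespace Rcpp;

// Normalized LMS adaptive FIR filter.
// x: reference input, d: desired signal, order: tap count, mu: step size.
// Returns the filter output y[n] = w(n) . [x[n], x[n-1], ..., x[n-order+1]],
// with w updated per sample by w += mu * e * u / (eps + ||u||^2).
// [[Rcpp::export(rng = false)]]
NumericVector nlms_filter(NumericVector x, NumericVector d, int order,
                          double mu, double eps = 1e-8) {
  int n = x.size();
  if (d.size() != n) stop("x and d must have the same length");
  if (order < 1) stop("order must be >= 1");
  if (mu <= 0 || mu > 1) stop("mu must be in (0, 1]");
  NumericVector y(n);
  std::vector<double> w(order, 0.0);
  std::vector<double> u(order, 0.0);
  for (int i = 0; i < n; ++i) {
    // shift the tapped delay line: u = [x[i], x[i-1], ...]
    for (int j = order - 1; j > 0; --j) u[j] = u[j - 1];
    u[0] = x[i];
    double yi = 0.0, norm2 = 0.0;
    for (int j = 0; j < order; ++j) {
      yi += w[j] * u[j];
      norm2 += u[j] * u[j];
    }
    y[i] = yi;
    double e = d[i] - yi;
    double g = mu * e / (eps + norm2);
    for (int j = 0; j < order; ++j) w[j] += g * u[j];
  }
  return y;
}
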