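// Direct-form II transposed IIR filter with initial conditions, the kernel
// behind zero-phase (forward-backward) Butterworth filtering.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".iir_filter")]]
NumericVector iir_filter(NumericVector b, NumericVector a, NumericVector x,
                         NumericVector zi) {
  int nb = b.size(), na = a.size();
  int k = std::max(na, nb) - 1;
  if (zi.size() != k) stop("zi must have length max(length(a), length(b)) - 1");
  std::vector<double> bb(k + 1, 0.0), aa(k + 1, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  if (aa[0] == 0) stop("a[1] must be nonzero");
  for (int i = 0; i <= k; ++i) { bb[i] /= aa[0]; }
  for (int i = k; i >= 0; --i) { aa[i] /= aa[0]; }
  std::vector<double> z(zi.begin(), zi.end());
  int n = x.size();
  NumericVector y(n);
  for (int t = 0; t < n; ++t) {
    double xt = x[t];
    double yt = bb[0] * xt + (k > 0 ? z[0] : 0.0);
    for (int i = 0; i < k - 1; ++i)
      z[i] = bb[i + 1] * xt + z[i + 1] - aa[i + 1] * yt;
    if (k > 0) z[k - 1] = bb[k] * xt - aa[k] * yt;
    y[t] = yt;
  }
  return y;
}
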