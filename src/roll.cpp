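#include <Rcpp.h>
using namespace Rcpp;

// Rolling standard deviation over right-aligned full windows of k samples.
// Windows containing any NA yield NA.  Input should be roughly centred by
// the caller so the running-sum variance update stays well conditioned.
// [[Rcpp::export]]
NumericVector roll_sd_c(NumericVector v, int k, bool sample_denom) {
  const int n = v.size();
  NumericVector out(n, NA_REAL);
  if (k < 2 || k > n) return out;
  double s = 0.0, s2 = 0.0;
  int bad = 0;
  for (int i = 0; i < n; ++i) {
    const double xi = v[i];
    if (ISNAN(xi)) ++bad; else { s += xi; s2 += xi * xi; }
    if (i >= k) {
      const double xo = v[i - k];
      if (ISNAN(xo)) --bad; else { s -= xo; s2 -= xo * xo; }
    }
    if (i >= k - 1 && bad == 0) {
      const double m = s / k;
      double var = s2 / k - m * m;
      if (var < 0) var = 0;
      if (sample_denom) var *= k / (k - 1.0);
      out[i] = std::sqrt(var);
    }
  }
  return out;
}
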