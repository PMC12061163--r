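#include <Rcpp.h>
using namespace Rcpp;

// Sample entropy (Richman & Moorman): -ln(A/B) where B counts pairs of
// m-length templates and A pairs of (m+1)-length templates within Chebyshev
// tolerance r. Both counts run over the N - m templates so that every
// m-template has an (m+1)-length extension. Self-matches are excluded.
// [[Rcpp::export]]
double sampen_cpp(NumericVector x, int m, double r) {
  int n = x.size();
  int nt = n - m;  // number of (m+1)-length templates
  if (nt < 2) return NA_REAL;
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double d = 0.0;
      bool ok = true;
      for (int k = 0; k < m; ++k) {
        double dk = std::abs(x[i + k] - x[j + k]);
        if (dk > d) d = dk;
        if (d > r) { ok = false; break; }
      }
      if (!ok) continue;
      B += 1.0;
      double dm = std::abs(x[i + m] - x[j + m]);
      if (dm <= r && d <= r) A += 1.0;
    }
  }
  if (B == 0.0 || A == 0.0) return NA_REAL;
  return -std::log(A / B);
}
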