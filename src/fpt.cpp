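#include <Rcpp.h>
using namespace Rcpp;

// First passage time beyond a circle of `radius` centred on each fix.
// Returns, per fix, the first time at which the trajectory exceeds the
// radius minus the fix time; Inf when the trajectory ends (or `cap`
// seconds elapse) without leaving the circle. Fixes are one worker's
// valid fixes in time order.

// [[Rcpp::export]]
NumericVector fpt_cpp(NumericVector t, NumericVector x, NumericVector y,
                      double radius, double cap) {
  const int n = t.size();
  NumericVector out(n, R_PosInf);
  const double r2 = radius * radius;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = x[j] - x[i], dy = y[j] - y[i];
      if (dx * dx + dy * dy > r2) { out[i] = t[j] - t[i]; break; }
      if (t[j] - t[i] > cap) break;  // censored at cap -> Inf
    }
  }
  return out;
}
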