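#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Sliding-window percentile with linear interpolation between order
// statistics (the same rule as stats::quantile type 7). The window at
// sample i is [i - half, i + half], clipped at the trace bounds, so edge
// windows shrink rather than pad. The sorted window is maintained
// incrementally (binary-search insert/erase), O(n * w) worst case.
// [[Rcpp::export]]
NumericVector sliding_percentile_cpp(NumericVector x, int half, double prob) {
  const int n = x.size();
  NumericVector out(n);
  if (n == 0) return out;
  std::vector<double> win;
  win.reserve(2 * half + 2);
  int lo = 0, hi = -1;  // current window is x[lo..hi]
  for (int i = 0; i < n; ++i) {
    const int nlo = std::max(0, i - half);
    const int nhi = std::min(n - 1, i + half);
    while (hi < nhi) {
      ++hi;
      win.insert(std::upper_bound(win.begin(), win.end(), x[hi]), x[hi]);
    }
    while (lo < nlo) {
      win.erase(std::lower_bound(win.begin(), win.end(), x[lo]));
      ++lo;
    }
    const int m = static_cast<int>(win.size());
    const double h = (m - 1) * prob;
    const int k = static_cast<int>(std::floor(h));
    const double g = h - k;
    if (g > 0.0 && k + 1 < m) {
      out[i] = win[k] + g * (win[k + 1] - win[k]);
    } else {
      out[i] = win[k];
    }
  }
  return out;
}
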