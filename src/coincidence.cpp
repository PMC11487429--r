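// Sliding-window coincidence sorter.
//
// Windows open at the earliest unconsumed single and span `window_ns`.
// Exactly two singles in a window form a candidate pair, which must pass
// the geometry acceptance (different panel, or circular sector difference
// >= min_diff on the ring); failing pairs are dropped. Windows with more
// than two singles are discarded entirely (killAll policy).
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
IntegerMatrix cpp_sort_coincidences(NumericVector t, IntegerVector group,
                                    double window_ns, int mode,
                                    int n_groups, int min_diff) {
  int n = t.size();
  for (int i = 1; i < n; ++i)
    if (t[i] < t[i - 1]) stop("singles must be time-sorted");
  std::vector<int> a, b;
  int i = 0;
  while (i < n) {
    int j = i + 1;
    while (j < n && t[j] - t[i] <= window_ns) ++j;
    int m = j - i;
    if (m == 2) {
      bool ok;
      if (mode == 0) ok = group[i] != group[i + 1];
      else {
        int d = std::abs(group[i] - group[i + 1]);
        d = std::min(d, n_groups - d);
        ok = d >= min_diff;
      }
      if (ok) { a.push_back(i + 1); b.push_back(i + 2); } // 1-based
    }
    i = (m == 1) ? i + 1 : j;
  }
  IntegerMatrix out(a.size(), 2);
  for (size_t r = 0; r < a.size(); ++r) { out(r, 0) = a[r]; out(r, 1) = b[r]; }
  return out;
}
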