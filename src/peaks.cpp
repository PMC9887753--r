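#include <Rcpp.h>
using namespace Rcpp;

// Local maxima with topographic prominence.
//
// A sample is a local maximum if it is strictly higher than the nearest
// differing neighbour on each side; a plateau top is reported at its first
// sample (ties break toward the earlier sample). Prominence of a peak of
// height h is h - max(lmin, rmin), where lmin (rmin) is the lowest value
// between the peak and the nearest strictly higher sample to the left
// (right), or the trace end if no higher sample exists on that side.
//
// [[Rcpp::export]]
List find_peaks_cpp(NumericVector y) {
  const int n = y.size();
  std::vector<int> idx;

  int i = 1;
  while (i < n - 1) {
    if (y[i] > y[i - 1]) {
      int j = i;
      while (j < n - 1 && y[j + 1] == y[i]) ++j;  // plateau run
      if (j < n - 1 && y[j + 1] < y[i]) idx.push_back(i);
      i = j + 1;
    } else {
      ++i;
    }
  }

  const int m = idx.size();
  IntegerVector out_idx(m);
  NumericVector out_h(m), out_prom(m);
  for (int p = 0; p < m; ++p) {
    const int k = idx[p];
    const double h = y[k];
    double lmin = h, rmin = h;
    for (int q = k - 1; q >= 0 && y[q] <= h; --q)
      if (y[q] < lmin) lmin = y[q];
    for (int q = k + 1; q < n && y[q] <= h; ++q)
      if (y[q] < rmin) rmin = y[q];
    out_idx[p] = k + 1;  // 1-based for R
    out_h[p] = h;
    out_prom[p] = h - std::max(lmin, rmin);
  }
  return List::create(_["index"] = out_idx, _["height"] = out_h,
                      _["prominence"] = out_prom);
}
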