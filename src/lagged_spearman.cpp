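#include <Rcpp.h>
#include <algorithm>
#include <numeric>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Midranks of the contiguous window v[a..b) of the full series v, derived
// from the precomputed global sort order `ord` of v (indices sorted by
// value, ties in stable index order). One O(n) pass per window instead of
// a per-window sort: walk the global order, keep indices inside the
// window, and assign average ranks to runs of equal values.
static void window_midranks(const std::vector<double>& v,
                            const std::vector<int>& ord,
                            int a, int b,
                            std::vector<int>& keep,
                            std::vector<double>& r) {
  keep.clear();
  for (int idx : ord)
    if (idx >= a && idx < b) keep.push_back(idx);
  const int m = (int) keep.size();
  int i = 0;
  while (i < m) {
    int j = i;
    while (j + 1 < m && v[keep[j + 1]] == v[keep[i]]) ++j;
    double rank = 0.5 * (i + j) + 1.0;
    for (int k = i; k <= j; ++k) r[keep[k] - a] = rank;
    i = j + 1;
  }
}

static double pearson(const std::vector<double>& a,
                      const std::vector<double>& b, int m) {
  double ma = 0, mb = 0;
  for (int i = 0; i < m; ++i) { ma += a[i]; mb += b[i]; }
  ma /= m; mb /= m;
  double sab = 0, saa = 0, sbb = 0;
  for (int i = 0; i < m; ++i) {
    double da = a[i] - ma, db = b[i] - mb;
    sab += da * db; saa += da * da; sbb += db * db;
  }
  if (saa <= 0 || sbb <= 0) return NA_REAL;
  return sab / std::sqrt(saa * sbb);
}

static std::vector<int> sort_order(const std::vector<double>& v) {
  std::vector<int> ord(v.size());
  std::iota(ord.begin(), ord.end(), 0);
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return v[a] < v[b]; });
  return ord;
}

// Spearman correlation of x(t) with y(t - lag) over the overlapping
// support, for each lag (in samples). Positive lag: x follows y.
// [[Rcpp::export]]
NumericVector lagged_spearman_cpp(NumericVector x, NumericVector y,
                                  IntegerVector lags, int min_overlap) {
  const int n = x.size();
  if (y.size() != n) stop("x and y must have equal length");
  std::vector<double> xv(x.begin(), x.end());
  std::vector<double> yv(y.begin(), y.end());
  const std::vector<int> ordx = sort_order(xv);
  const std::vector<int> ordy = sort_order(yv);
  NumericVector out(lags.size());
  std::vector<double> rx(n), ry(n);
  std::vector<int> keep;
  keep.reserve(n);
  for (int L = 0; L < lags.size(); ++L) {
    const int lag = lags[L];
    const int a = std::max(0, lag);        // 0-based start in x
    const int b = std::min(n, n + lag);    // 0-based end (exclusive) in x
    const int m = b - a;
    if (m < min_overlap) { out[L] = NA_REAL; continue; }
    window_midranks(xv, ordx, a, b, keep, rx);
    window_midranks(yv, ordy, a - lag, b - lag, keep, ry);
    out[L] = pearson(rx, ry, m);
  }
  return out;
}
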