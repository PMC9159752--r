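#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Kendall's tau-a: (concordant - discordant) / (m*(m-1)/2), ties counting as
// neither concordant nor discordant; the denominator is the full pair count
// (tau-a, not tau-b). Computed in O(m log m) with Knight's algorithm:
// sort by (x, y), count tie pairs in x (n1), in y (n2), in both (n3), and
// count discordant pairs as strict inversions of y by merge sort; then
// C - D = n0 - n1 - n2 + n3 - 2D.

static long long merge_count(std::vector<double>& v, std::vector<double>& buf,
                             size_t lo, size_t hi) {
  if (hi - lo < 2) return 0;
  size_t mid = lo + (hi - lo) / 2;
  long long cnt = merge_count(v, buf, lo, mid) + merge_count(v, buf, mid, hi);
  size_t i = lo, j = mid, k = lo;
  while (i < mid && j < hi) {
    if (v[j] < v[i]) { // strict inversion only: ties are not discordant
      cnt += (long long)(mid - i);
      buf[k++] = v[j++];
    } else {
      buf[k++] = v[i++];
    }
  }
  while (i < mid) buf[k++] = v[i++];
  while (j < hi) buf[k++] = v[j++];
  std::copy(buf.begin() + lo, buf.begin() + hi, v.begin() + lo);
  return cnt;
}

// [[Rcpp::export]]
List cpp_kendall_tau_a(NumericVector x, NumericVector y) {
  R_xlen_t m = x.size();
  if (y.size() != m) stop("x and y must have equal length");
  if (m < 2) stop("need at least 2 observations");
  std::vector<size_t> ord(m);
  for (R_xlen_t i = 0; i < m; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](size_t a, size_t b) {
    if (x[a] != x[b]) return x[a] < x[b];
    return y[a] < y[b];
  });
  // tie pair counts among x (n1) and among (x, y) jointly (n3)
  long long n1 = 0, n3 = 0;
  {
    R_xlen_t i = 0;
    while (i < m) {
      R_xlen_t j = i;
      while (j < m && x[ord[j]] == x[ord[i]]) ++j;
      long long t = j - i;
      n1 += t * (t - 1) / 2;
      R_xlen_t a = i;
      while (a < j) {
        R_xlen_t b = a;
        while (b < j && y[ord[b]] == y[ord[a]]) ++b;
        long long u = b - a;
        n3 += u * (u - 1) / 2;
        a = b;
      }
      i = j;
    }
  }
  // tie pair count among y (n2)
  std::vector<double> ys(m);
  for (R_xlen_t i = 0; i < m; ++i) ys[i] = y[i];
  std::sort(ys.begin(), ys.end());
  long long n2 = 0;
  {
    R_xlen_t i = 0;
    while (i < m) {
      R_xlen_t j = i;
      while (j < m && ys[j] == ys[i]) ++j;
      long long t = j - i;
      n2 += t * (t - 1) / 2;
      i = j;
    }
  }
  // discordant pairs: strict inversions of y in (x, y)-sorted order
  std::vector<double> yseq(m), buf(m);
  for (R_xlen_t i = 0; i < m; ++i) yseq[i] = y[ord[i]];
  long long D = merge_count(yseq, buf, 0, m);
  long long n0 = (long long)m * (m - 1) / 2;
  long long cd = n0 - n1 - n2 + n3 - 2 * D;
  return List::create(_["tau_a"] = (double)cd / (double)n0,
                      _["n_pairs_compared"] = (double)n0);
}
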