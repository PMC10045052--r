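#ifndef PASDIST_CORE_H
#define PASDIST_CORE_H

#include <string>
#include <vector>
#include <algorithm>
#include <climits>
#include <cstdint>

namespace pasdist {

const int PD_INF = INT_MAX / 4;

// Unified edit-distance kernel.
//
// Computes the margin-gap distance between x and y: unit-cost edit distance
// where on each margin (a maximal run of leading or trailing gap columns
// falling in one string) the first t gap symbols are free.  t = 0 gives the
// plain Levenshtein distance.
//
// If bound >= 0, only values <= bound are of interest; returns -1 as soon as
// the distance provably exceeds bound (Ukkonen-style band of half-width
// bound + t + 1 plus monotone row-minimum early abandon).  bound < 0 means
// unbounded (exact value always returned).
inline int mg_core(const char* x, int m, const char* y, int n, int t,
                   long bound_in) {
  long bound = bound_in < 0 ? (long)PD_INF : bound_in;
  long h = bound + t + 1;  // band half-width: cells |i-j| > h cost > bound
  if (h > (long)(m > n ? m : n) + 1) h = (long)(m > n ? m : n) + 1;

  std::vector<int> prev((size_t)n + 2, PD_INF), cur((size_t)n + 2, PD_INF);
  int prevlo = 0, prevhi = (int)std::min<long>(n, h);
  for (int j = prevlo; j <= prevhi; ++j) prev[j] = std::max(0, j - t);

  // candidates D[i][n] + max(0, (m - i) - t)  (trailing gaps on x side)
  long best_x_trail = PD_INF;
  if (n <= prevhi) best_x_trail = (long)prev[n] + std::max(0, m - t);

  int lastlo = prevlo, lasthi = prevhi;  // band of the row stored in `prev`
  for (int i = 1; i <= m; ++i) {
    int jlo = (int)std::max<long>(0, (long)i - h);
    int jhi = (int)std::min<long>(n, (long)i + h);
    if (jlo > 0) cur[jlo - 1] = PD_INF;
    long rowmin = PD_INF;
    for (int j = jlo; j <= jhi; ++j) {
      int d;
      if (j == 0) {
        d = std::max(0, i - t);
      } else {
        int diag = (j - 1 >= prevlo && j - 1 <= prevhi) ? prev[j - 1] : PD_INF;
        int up   = (j     >= prevlo && j     <= prevhi) ? prev[j]     : PD_INF;
        int left = (j - 1 >= jlo) ? cur[j - 1] : PD_INF;
        d = diag + (x[i - 1] == y[j - 1] ? 0 : 1);
        if (up + 1 < d) d = up + 1;
        if (left + 1 < d) d = left + 1;
        if (d > PD_INF) d = PD_INF;
      }
      cur[j] = d;
      if (d < rowmin) rowmin = d;
      if (j == n) {
        long cand = (long)d + std::max(0, (m - i) - t);
        if (cand < best_x_trail) best_x_trail = cand;
      }
    }
    if (jhi < n) cur[jhi + 1] = PD_INF;
    std::swap(prev, cur);
    prevlo = jlo; prevhi = jhi;
    lastlo = jlo; lasthi = jhi;
    if (rowmin > bound && best_x_trail > bound) return -1;
  }

  // trailing gaps on y side: min_j D[m][j] + max(0, (n - j) - t)
  long best = best_x_trail;
  for (int j = lastlo; j <= lasthi; ++j) {
    long cand = (long)prev[j] + std::max(0, (n - j) - t);
    if (cand < best) best = cand;
  }
  if (bound_in >= 0 && best > bound) return -1;
  return (int)best;
}

inline int mg_core(const std::string& x, const std::string& y, int t,
                   long bound) {
  return mg_core(x.data(), (int)x.size(), y.data(), (int)y.size(), t, bound);
}

// Exact Levenshtein via iterative band doubling (always terminates with the
// exact value).
inline int lev_exact(const char* x, int m, const char* y, int n) {
  long b = std::max(1, std::abs(m - n));
  for (;;) {
    int r = mg_core(x, m, y, n, 0, b);
    if (r >= 0) return r;
    b *= 2;
  }
}

inline int lev_exact(const std::string& x, const std::string& y) {
  return lev_exact(x.data(), (int)x.size(), y.data(), (int)y.size());
}

// 5-letter code: a,c,g,t,n -> 0..4 (anything unexpected behaves like n).
inline int code5(char ch) {
  switch (ch) {
    case 'a': return 0;
    case 'c': return 1;
    case 'g': return 2;
    case 't': return 3;
    default:  return 4;
  }
}

inline int64_t pow5(int q) {
  int64_t v = 1;
  for (int i = 0; i < q; ++i) v *= 5;
  return v;
}

inline long pow4l(int q) {
  long v = 1;
  for (int i = 0; i < q; ++i) v *= 4;
  return v;
}

}  // namespace pasdist

#endif
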