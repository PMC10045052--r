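#include <Rcpp.h>
#include "core.h"

using namespace Rcpp;
using namespace pasdist;

namespace {

// Candidate comparison for the contig-contig match: minimize the
// post-normalized distance edit / max(la, lb); ties prefer the longer
// overlap, then the smaller (a_start, b_start).  Exact rational comparison.
struct Cand {
  int a_start, a_end, b_start, b_end, edit;
  bool set = false;
  int la() const { return a_end - a_start; }
  int lb() const { return b_end - b_start; }
  int maxlen() const { return la() > lb() ? la() : lb(); }
};

bool better(const Cand& x, const Cand& y) {
  // is x better than y?
  if (!y.set) return true;
  long long lhs = (long long)x.edit * y.maxlen();
  long long rhs = (long long)y.edit * x.maxlen();
  if (lhs != rhs) return lhs < rhs;
  if (x.maxlen() != y.maxlen()) return x.maxlen() > y.maxlen();
  if (x.la() + x.lb() != y.la() + y.lb()) return x.la() + x.lb() > y.la() + y.lb();
  if (x.a_start != y.a_start) return x.a_start < y.a_start;
  return x.b_start < y.b_start;
}

void consider(Cand& best, int as, int ae, int bs, int be, int edit) {
  Cand c;
  c.a_start = as; c.a_end = ae; c.b_start = bs; c.b_end = be;
  c.edit = edit; c.set = true;
  if (better(c, best)) best = c;
}

// full Wagner-Fischer table of x vs y (row-major, (m+1) x (n+1))
void wf_table(const std::string& x, const std::string& y,
              std::vector<int>& D) {
  int m = (int)x.size(), n = (int)y.size();
  D.assign((size_t)(m + 1) * (n + 1), 0);
  for (int j = 0; j <= n; ++j) D[j] = j;
  for (int i = 1; i <= m; ++i) {
    D[(size_t)i * (n + 1)] = i;
    for (int j = 1; j <= n; ++j) {
      int d = D[(size_t)(i - 1) * (n + 1) + j - 1] +
              (x[i - 1] == y[j - 1] ? 0 : 1);
      int up = D[(size_t)(i - 1) * (n + 1) + j] + 1;
      int left = D[(size_t)i * (n + 1) + j - 1] + 1;
      if (up < d) d = up;
      if (left < d) d = left;
      D[(size_t)i * (n + 1) + j] = d;
    }
  }
}

}  // namespace

// Exhaustive contig-contig match over the candidate set
//   suff(alpha) x pref(beta)  U  pref(alpha) x suff(beta)
//   U  sub(alpha) x {beta}    U  {alpha} x sub(beta)
// with both candidate lengths >= min_overlap.  One DP table per suffix
// start yields a whole family of candidates (last row: full suffix vs all
// prefixes; last column: substrings vs the full other contig).
// [[Rcpp::export]]
List cpp_match_pair_exact(std::string alpha, std::string beta,
                          int min_overlap) {
  int na = (int)alpha.size(), nb = (int)beta.size();
  Cand best;
  std::vector<int> D;
  if (na >= min_overlap && nb >= min_overlap) {
    // suffixes of alpha: DP(alpha[i..], beta)
    for (int i = 0; i + min_overlap <= na; ++i) {
      std::string suf = alpha.substr(i);
      wf_table(suf, beta, D);
      int m = na - i;
      // suff(alpha) x pref(beta): last row
      for (int j = min_overlap; j <= nb; ++j)
        consider(best, i, na, 0, j, D[(size_t)m * (nb + 1) + j]);
      // sub(alpha) x {beta}: last column (r = substring length)
      for (int r = min_overlap; r <= m; ++r)
        consider(best, i, i + r, 0, nb, D[(size_t)r * (nb + 1) + nb]);
    }
    // suffixes of beta: DP(beta[j..], alpha)
    for (int j = 0; j + min_overlap <= nb; ++j) {
      std::string suf = beta.substr(j);
      wf_table(suf, alpha, D);
      int m = nb - j;
      // pref(alpha) x suff(beta): last row
      for (int i = min_overlap; i <= na; ++i)
        consider(best, 0, i, j, nb, D[(size_t)m * (na + 1) + i]);
      // {alpha} x sub(beta): last column
      for (int r = min_overlap; r <= m; ++r)
        consider(best, 0, na, j, j + r, D[(size_t)r * (na + 1) + na]);
    }
  }
  if (!best.set) return List::create();
  return List::create(_["a_start"] = best.a_start, _["a_end"] = best.a_end,
                      _["b_start"] = best.b_start, _["b_end"] = best.b_end,
                      _["edit"] = best.edit);
}
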