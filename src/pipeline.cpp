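#include <Rcpp.h>
#include <unordered_map>
#include <queue>
#include "core.h"

using namespace Rcpp;
using namespace pasdist;

namespace {

typedef std::vector<std::pair<int64_t, int>> GramList;  // sorted (gram, count)

GramList gram_list(const std::string& s, int q) {
  std::unordered_map<int64_t, int> cnt;
  int n = (int)s.size();
  if (n >= q) {
    int64_t mod = pow5(q - 1), val = 0;
    for (int i = 0; i < n; ++i) {
      if (i >= q) val -= code5(s[i - q]) * mod;
      val = val * 5 + code5(s[i]);
      if (i >= q - 1) cnt[val]++;
    }
  }
  GramList out(cnt.begin(), cnt.end());
  std::sort(out.begin(), out.end());
  return out;
}

long l1_merge(const GramList& a, const GramList& b) {
  long d = 0;
  size_t i = 0, j = 0;
  while (i < a.size() && j < b.size()) {
    if (a[i].first < b[j].first) d += a[i++].second;
    else if (a[i].first > b[j].first) d += b[j++].second;
    else { d += std::abs(a[i].second - b[j].second); ++i; ++j; }
  }
  while (i < a.size()) d += a[i++].second;
  while (j < b.size()) d += b[j++].second;
  return d;
}

// Sliding q-gram distances between `read` and every length-|read| window of
// `contig` (offsets 0 .. |contig|-|read|).
std::vector<long> sliding_qd(const std::string& read,
                             const std::string& contig, int q) {
  int nr = (int)read.size(), nc = (int)contig.size();
  std::vector<long> out;
  if (nc < nr) return out;
  std::unordered_map<int64_t, int> diff;
  long l1 = 0;
  for (auto& kv : gram_list(read, q)) { diff[kv.first] = kv.second; l1 += kv.second; }
  auto upd = [&](int64_t g, int delta) {
    int& v = diff[g];
    l1 -= std::abs(v);
    v += delta;
    l1 += std::abs(v);
    if (v == 0) diff.erase(g);
  };
  auto gram_at = [&](int pos) {
    int64_t val = 0;
    for (int k = 0; k < q; ++k) val = val * 5 + code5(contig[pos + k]);
    return val;
  };
  int n_off = nc - nr + 1;
  out.resize((size_t)n_off);
  if (nr >= q) for (int p = 0; p <= nr - q; ++p) upd(gram_at(p), -1);
  out[0] = l1;
  for (int o = 1; o < n_off; ++o) {
    if (nr >= q) { upd(gram_at(o - 1), +1); upd(gram_at(o + nr - q), -1); }
    out[o] = l1;
  }
  return out;
}

// Margin-gap distance of x against every prefix y[0..n') of y with
// n' in [lo, hi], minimized; banded by `bound` (half-width bound + t + 1)
// with row-minimum early abandon.  Returns an exact candidate value when it
// is < bound, otherwise some value >= bound (possibly PD_INF).
int mg_prefix_min(const std::string& x, const std::string& y, int t,
                  int lo, int hi, int bound) {
  int m = (int)x.size(), n = (int)y.size();
  if (hi > n) hi = n;
  if (lo < 1) lo = 1;
  if (lo > hi) return PD_INF;
  long b = bound < 0 ? (long)PD_INF : bound;
  long h = b + t + 1;
  if (h > (long)(m > n ? m : n) + 1) h = (long)(m > n ? m : n) + 1;
  std::vector<int> prev((size_t)n + 1, PD_INF), cur((size_t)n + 1, PD_INF);
  std::vector<long> colbest((size_t)n + 1, PD_INF);
  int prevlo = 0, prevhi = (int)std::min<long>(n, h);
  for (int j = prevlo; j <= prevhi; ++j) {
    prev[j] = std::max(0, j - t);
    long cand = (long)prev[j] + std::max(0, m - t);
    if (cand < colbest[j]) colbest[j] = cand;
  }
  bool alive = true;
  int lastlo = prevlo, lasthi = prevhi;
  for (int i = 1; i <= m && alive; ++i) {
    int jlo = (int)std::max<long>(0, (long)i - h);
    int jhi = (int)std::min<long>(n, (long)i + h);
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
      long cand = (long)d + std::max(0, (m - i) - t);
      if (cand < colbest[j]) colbest[j] = cand;
    }
    std::swap(prev, cur);
    prevlo = jlo; prevhi = jhi;
    lastlo = jlo; lasthi = jhi;
    if (rowmin >= b) alive = false;  // colbest candidates already collected
  }
  long best = PD_INF;
  for (int np = lo; np <= hi; ++np)
    if (colbest[np] < best) best = colbest[np];
  if (alive) {
    // trailing gaps on the prefix (y) side
    for (int np = lo; np <= hi; ++np) {
      int j0 = std::max(lastlo, np - t), j1 = std::min(lasthi, np);
      for (int j = j0; j <= j1; ++j)
        if ((long)prev[j] < best) best = prev[j];
      int j2 = std::min(lasthi, np - t - 1);
      for (int j = lastlo; j <= j2; ++j) {
        long cand = (long)prev[j] + (np - j - t);
        if (cand < best) best = cand;
      }
    }
  }
  return (int)std::min<long>(best, PD_INF);
}

inline long ceil_div_clamp(long num, long den) {
  if (num <= 0) return 0;
  return (num + den - 1) / den;
}

// Free-window-start lower-bound DP: L[i][j] = minimal cost of any partial
// margin-gap alignment of a[1..i] against a window of beta contained in
// beta[..j], with window start free (choosing a later start subsumes free
// or paid leading window gaps) and read-side leading margin discounted.
// bestend[j] collects min_i L[i][j] + max(0, (l - i) - t), a valid lower
// bound on the margin-gap cost of any window whose alignment ends at j.
void window_lb_dp(const std::string& a, const std::string& beta, int t,
                  std::vector<long>& bestend) {
  int l = (int)a.size(), nb = (int)beta.size();
  bestend.assign((size_t)nb + 1, 0);
  std::vector<int> prev((size_t)nb + 1, 0), cur((size_t)nb + 1, 0);
  long tr0 = std::max(0, l - t);
  for (int j = 0; j <= nb; ++j) bestend[j] = tr0;
  for (int i = 1; i <= l; ++i) {
    int restart = std::max(0, i - t);
    cur[0] = restart;
    long tr = std::max(0, (l - i) - t);
    if (cur[0] + tr < bestend[0]) bestend[0] = cur[0] + tr;
    for (int j = 1; j <= nb; ++j) {
      int d = prev[j - 1] + (a[i - 1] == beta[j - 1] ? 0 : 1);
      if (prev[j] + 1 < d) d = prev[j] + 1;
      if (cur[j - 1] + 1 < d) d = cur[j - 1] + 1;
      if (restart < d) d = restart;
      cur[j] = d;
      long v = (long)d + tr;
      if (v < bestend[j]) bestend[j] = v;
    }
    std::swap(prev, cur);
  }
}

// Mirror image of window_lb_dp: beststart[j] is a lower bound on the
// margin-gap cost of any window of beta STARTING at j, obtained by running
// the same free-boundary DP on the reversed strings (free window end,
// discounted read trailing margin).
void window_lb_dp_rev(const std::string& a, const std::string& beta, int t,
                      std::vector<long>& beststart) {
  std::string ar(a.rbegin(), a.rend());
  std::string br(beta.rbegin(), beta.rend());
  std::vector<long> be;
  window_lb_dp(ar, br, t, be);
  int nb = (int)beta.size();
  beststart.assign((size_t)nb, 0);
  for (int j = 0; j < nb; ++j) beststart[j] = be[(size_t)(nb - j)];
}

// Prepared per-(read, contig) candidate state for the fast window search.
struct RcWork {
  std::vector<long> lb;   // per-start lower bound
  std::vector<int> ord;   // starts in ascending bound order
  long ubound = 0;        // min over starts (contig-level lower bound)
};

// Build per-start lower bounds: the per-start q-gram bound
// (qd - 3t)/(2q) (up to t grams for the window length range, up to 2t for
// the discounted margins) sharpened by the free-boundary DP anchored at
// the window start.
void rc_prepare(const std::string& a, const std::string& beta, int t, int q,
                const std::vector<long>& qd, RcWork& w) {
  int l = (int)a.size(), nb = (int)beta.size();
  int lo = std::max(1, l - t);
  int n_off = (int)qd.size();
  std::vector<long> beststart;
  window_lb_dp_rev(a, beta, t, beststart);
  // leading window gaps let a window starting at i behave like one starting
  // at i+g, free for g <= t and costing g-t beyond:
  // bound(i) = min_g beststart[i+g] + max(0, g-t)
  std::vector<long> decay((size_t)nb + 1, PD_INF);  // min_h bs[k+h] + h
  for (int k = nb - 1; k >= 0; --k)
    decay[k] = std::min(beststart[k], decay[k + 1] + 1);
  int n_starts = nb - lo + 1;
  w.lb.assign((size_t)n_starts, 0);
  for (int i = 0; i < n_starts; ++i) {
    long wlb = (i + t + 1 <= nb) ? decay[i + t + 1] + 1 : PD_INF;
    for (int g = 0; g <= t && i + g < nb; ++g)
      if (beststart[i + g] < wlb) wlb = beststart[i + g];
    long qlb = ceil_div_clamp(qd[std::min(i, n_off - 1)] - 3L * t, 2L * q);
    w.lb[i] = std::max(qlb, wlb);
  }
  w.ord.resize((size_t)n_starts);
  for (int i = 0; i < n_starts; ++i) w.ord[i] = i;
  std::sort(w.ord.begin(), w.ord.end(),
            [&](int x, int y) { return w.lb[x] < w.lb[y]; });
  w.ubound = n_starts > 0 ? w.lb[w.ord[0]] : 0;
}

// Exact per-start evaluation in ascending bound order; returns the exact
// minimum whenever it is < bound (sound inside an outer minimum).
int rc_run(const std::string& a, const std::string& beta, int t,
           const RcWork& w, int bound) {
  int l = (int)a.size(), nb = (int)beta.size();
  int lo = std::max(1, l - t), hi = l + t;
  int best = PD_INF;
  for (int i : w.ord) {
    if (w.lb[i] >= (long)std::min(best, bound)) break;
    int hi_i = std::min(hi, nb - i);
    if (hi_i < lo) continue;
    std::string y = beta.substr(i, hi_i);
    int r = mg_prefix_min(a, y, t, lo, hi_i, std::min(best, bound));
    if (r < best) best = r;
    if (best == 0) break;
  }
  return best;
}

// dist_rc: minimum over windows of beta with length in [l-t, l+t] of the
// margin-gap distance to read a (whole contig when |beta| < l-t).  Fast
// mode localizes candidate window starts with the sliding q-gram distance
// sharpened by a free-boundary DP bound and evaluates the exact margin-gap
// DP in ascending bound order until the bounds exceed the running minimum,
// so it returns exactly the exhaustive minimum.  `bound`: values >= bound
// need not be exact; pass -1 for the true minimum.
int dist_rc_core(const std::string& a, const std::string& beta, int t, int q,
                 bool exact, int bound_in) {
  int l = (int)a.size(), nb = (int)beta.size();
  if (nb < 1) return PD_INF;
  int lo = std::max(1, l - t), hi = l + t;
  if (nb < lo) return mg_core(a, beta, t, -1);
  int bound = bound_in < 0 ? PD_INF : bound_in;
  if (exact || nb < l) {
    int best = PD_INF;
    for (int i = 0; i + lo <= nb; ++i) {
      int hi_i = std::min(hi, nb - i);
      if (hi_i < lo) continue;
      std::string y = beta.substr(i, hi_i);
      int r = mg_prefix_min(a, y, t, lo, hi_i, std::min(best, bound));
      if (r < best) best = r;
    }
    return best;
  }
  std::vector<long> qd = sliding_qd(a, beta, q);
  long qmin = *std::min_element(qd.begin(), qd.end());
  if (ceil_div_clamp(qmin - 3L * t, 2L * q) >= (long)bound)
    return PD_INF;
  RcWork w;
  rc_prepare(a, beta, t, q, qd, w);
  if (w.ubound >= (long)bound) return PD_INF;
  return rc_run(a, beta, t, w, bound);
}

}  // namespace

// [[Rcpp::export]]
int cpp_dist_rc(std::string a, std::string beta, int t, int q, bool exact) {
  return dist_rc_core(a, beta, t, q, exact, -1);
}

// [[Rcpp::export]]
IntegerVector cpp_dist_rc_many(CharacterVector reads, std::string beta,
                               int t, int q, bool exact) {
  int n = reads.size();
  IntegerVector out(n);
  for (int k = 0; k < n; ++k)
    out[k] = dist_rc_core(as<std::string>(reads[k]), beta, t, q, exact, -1);
  return out;
}

// Sum of the k smallest dist_rc(b, alpha_res) over reads b, with missing
// reads charged l each when k exceeds the bag size.  Reads are processed in
// ascending order of an optimistic q-gram lower bound so exact DP work
// concentrates on plausible reads; the result equals brute-force selection.
// [[Rcpp::export]]
double cpp_dist_cR(CharacterVector reads, std::string alpha_res, int t,
                   int q, bool exact, int k, int l, bool pad_missing) {
  int n = reads.size();
  if (k <= 0) return 0.0;
  std::vector<std::string> B((size_t)n);
  for (int j = 0; j < n; ++j) B[j] = as<std::string>(reads[j]);
  int take = std::min(k, n);
  std::vector<int> vals;
  if (take > 0) {
    // optimistic lower bound per read from its best sliding offset
    std::vector<long> lb((size_t)n, 0);
    std::vector<int> ord((size_t)n);
    for (int j = 0; j < n; ++j) {
      ord[j] = j;
      std::vector<long> qd = sliding_qd(B[j], alpha_res, q);
      if (!qd.empty()) {
        long qmin = *std::min_element(qd.begin(), qd.end());
        lb[j] = ceil_div_clamp(qmin - 3L * t, 2L * q);
      }
    }
    std::sort(ord.begin(), ord.end(),
              [&](int x, int y) { return lb[x] < lb[y]; });
    // max-heap of the `take` smallest exact values
    std::priority_queue<int> heap;
    for (int j : ord) {
      int cur_bound = ((int)heap.size() == take) ? heap.top() : PD_INF;
      if ((int)heap.size() == take && lb[j] >= cur_bound) break;
      int r = dist_rc_core(B[j], alpha_res, t, q, exact,
                           cur_bound == PD_INF ? -1 : cur_bound);
      if ((int)heap.size() < take) heap.push(r);
      else if (r < heap.top()) { heap.pop(); heap.push(r); }
    }
    while (!heap.empty()) { vals.push_back(heap.top()); heap.pop(); }
  }
  double total = 0.0;
  for (int v : vals) total += v;
  if (k > n && pad_missing) total += (double)(k - n) * l;
  return total;
}

// Monge-Elkan distance (1/|RA|) sum_a min_b dist_rr(a, b) where dist_rr is
// the margin-gap distance with budget t.  use_filter restricts the inner
// minimum to reads of RB tied at the minimal q-gram distance to a, resolved
// by exact DP; otherwise all of RB is scanned (with sound early abandon,
// which never changes the minimum).
// [[Rcpp::export]]
double cpp_monge_elkan(CharacterVector RA, CharacterVector RB, int t, int q,
                       bool use_filter) {
  int na = RA.size(), nb = RB.size();
  if (na == 0 || nb == 0) stop("both read bags must be non-empty");
  std::vector<std::string> A(na), B(nb);
  for (int i = 0; i < na; ++i) A[i] = as<std::string>(RA[i]);
  for (int j = 0; j < nb; ++j) B[j] = as<std::string>(RB[j]);
  std::vector<GramList> gb(nb);
  for (int j = 0; j < nb; ++j) gb[j] = gram_list(B[j], q);
  double total = 0.0;
  std::vector<long> qd((size_t)nb);
  std::vector<int> ord((size_t)nb);
  for (int i = 0; i < na; ++i) {
    GramList ga = gram_list(A[i], q);
    for (int j = 0; j < nb; ++j) qd[j] = l1_merge(ga, gb[j]);
    int best = PD_INF;
    if (use_filter) {
      // all reads tied at the minimal q-gram distance first, then any
      // candidate whose q-gram lower bound could still beat the best;
      // the retained set is a superset of the tied minimizers and the
      // result provably equals the exhaustive inner minimum
      for (int j = 0; j < nb; ++j) ord[j] = j;
      std::sort(ord.begin(), ord.end(),
                [&](int x, int y) { return qd[x] < qd[y]; });
      for (int j : ord) {
        if (best == 0) break;
        // equal-length reads: only the two read-side margins are discounted
        if (ceil_div_clamp(qd[j] - 2L * t, 2L * q) >= (long)best) break;
        int r = mg_core(A[i], B[j], t, best == PD_INF ? -1 : (long)best);
        if (r >= 0 && r < best) best = r;
      }
    } else {
      for (int j = 0; j < nb; ++j) ord[j] = j;
      std::sort(ord.begin(), ord.end(),
                [&](int x, int y) { return qd[x] < qd[y]; });
      for (int j : ord) {
        if (best == 0) break;
        int r = mg_core(A[i], B[j], t, best == PD_INF ? -1 : (long)best);
        if (r >= 0 && r < best) best = r;
      }
    }
    total += best;
  }
  return total / na;
}

// sum over a in RA of min(min_b in RB dist_rr(a,b), min_beta in CB
// dist_rc(a, beta)).  Both branches are exact minima (the q-gram orderings
// only steer early abandonment); `exact` switches the read-contig branch to
// plain exhaustive enumeration.
// [[Rcpp::export]]
double cpp_sum_dist_rT(CharacterVector RA, CharacterVector RB,
                       CharacterVector CB, int t, int q, bool exact) {
  int na = RA.size(), nb = RB.size(), ncont = CB.size();
  if (na == 0) return 0.0;
  if (nb == 0 && ncont == 0)
    stop("target sample has neither reads nor contigs");
  std::vector<std::string> A(na), B(nb), C(ncont);
  for (int i = 0; i < na; ++i) A[i] = as<std::string>(RA[i]);
  for (int j = 0; j < nb; ++j) B[j] = as<std::string>(RB[j]);
  for (int j = 0; j < ncont; ++j) C[j] = as<std::string>(CB[j]);
  std::vector<GramList> gb(nb);
  for (int j = 0; j < nb; ++j) gb[j] = gram_list(B[j], q);
  double total = 0.0;
  std::vector<long> qd((size_t)nb);
  std::vector<int> ord((size_t)nb);
  // Lazy best-first merge over both branches: every candidate (target read
  // or contig) carries a cheap q-gram lower bound; the candidate with the
  // smallest pending bound is processed next, where "processing" a contig
  // first refines its bound with the free-boundary DP and only then runs
  // the exact per-start search.  Heavy exact work therefore happens only
  // for candidates whose bound still beats the running minimum, and the
  // final value is the exact minimum over both branches.
  for (int i = 0; i < na; ++i) {
    int best = PD_INF;
    int p = 0;  // pointer into the rr candidate order
    if (nb > 0) {
      GramList ga = gram_list(A[i], q);
      for (int j = 0; j < nb; ++j) qd[j] = l1_merge(ga, gb[j]);
      for (int j = 0; j < nb; ++j) ord[j] = j;
      std::sort(ord.begin(), ord.end(),
                [&](int x, int y) { return qd[x] < qd[y]; });
    }
    std::vector<long> cbound((size_t)ncont, 0);
    std::vector<int> cstage((size_t)ncont, 0);  // 0 probe, 1 run, 2 done
    std::vector<std::vector<long>> cqd((size_t)ncont);
    std::vector<RcWork> cwork((size_t)ncont);
    int l = (int)A[i].size();
    for (int j = 0; j < ncont; ++j) {
      if (exact || (int)C[j].size() < l) { cbound[j] = 0; continue; }
      cqd[j] = sliding_qd(A[i], C[j], q);
      long qmin = *std::min_element(cqd[j].begin(), cqd[j].end());
      cbound[j] = ceil_div_clamp(qmin - 3L * t, 2L * q);
    }
    for (;;) {
      if (best == 0) break;
      long rr_next = PD_INF;
      while (p < nb) {
        rr_next = ceil_div_clamp(qd[ord[p]] - 2L * t, 2L * q);
        break;
      }
      if (p >= nb) rr_next = PD_INF;
      int cj = -1;
      long c_next = PD_INF;
      for (int j = 0; j < ncont; ++j)
        if (cstage[j] != 2 && cbound[j] < c_next) { c_next = cbound[j]; cj = j; }
      long nxt = std::min(rr_next, c_next);
      if (nxt >= (long)best) break;
      if (rr_next <= c_next) {
        int r = mg_core(A[i], B[ord[p]], t, (long)best);
        if (r >= 0 && r < best) best = r;
        ++p;
      } else if (cstage[cj] == 0 && !cqd[cj].empty()) {
        rc_prepare(A[i], C[cj], t, q, cqd[cj], cwork[cj]);
        cbound[cj] = std::max(cbound[cj], cwork[cj].ubound);
        cstage[cj] = 1;
      } else if (cstage[cj] == 1 && !cqd[cj].empty()) {
        int r = rc_run(A[i], C[cj], t, cwork[cj], best);
        if (r < best) best = r;
        cstage[cj] = 2;
      } else {
        // exact mode or contig shorter than the read: direct evaluation
        int r = dist_rc_core(A[i], C[cj], t, q, exact, best);
        if (r < best) best = r;
        cstage[cj] = 2;
      }
    }
    total += best;
  }
  return total;
}
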