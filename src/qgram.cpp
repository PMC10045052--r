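#include <Rcpp.h>
#include <unordered_map>
#include "core.h"

using namespace Rcpp;
using namespace pasdist;

namespace {

// gram counts of s as map from base-5 code to count
void gram_counts(const std::string& s, int q,
                 std::unordered_map<int64_t, int>& out) {
  int n = (int)s.size();
  if (n < q) return;
  int64_t mod = pow5(q - 1);
  int64_t val = 0;
  for (int i = 0; i < n; ++i) {
    if (i >= q) val -= code5(s[i - q]) * mod;
    val = (i >= q ? val : val) * 5 + code5(s[i]);
    if (i >= q - 1) out[val]++;
  }
}

std::string decode_gram(int64_t code, int q) {
  static const char letters[] = "acgtn";
  std::string g(q, 'a');
  for (int i = q - 1; i >= 0; --i) {
    g[i] = letters[code % 5];
    code /= 5;
  }
  return g;
}

// incremental L1 tracker over count differences (A side minus B side)
struct DiffL1 {
  std::unordered_map<int64_t, int> diff;
  long l1 = 0;
  void add(int64_t g, int delta) {
    int& v = diff[g];
    l1 -= std::abs(v);
    v += delta;
    l1 += std::abs(v);
    if (v == 0) diff.erase(g);
  }
};

inline int64_t gram_at(const std::string& s, int pos, int q) {
  int64_t val = 0;
  for (int i = 0; i < q; ++i) val = val * 5 + code5(s[pos + i]);
  return val;
}

}  // namespace

// [[Rcpp::export]]
List cpp_qgram_profile(std::string s, int q) {
  std::unordered_map<int64_t, int> cnt;
  gram_counts(s, q, cnt);
  std::vector<std::pair<int64_t, int>> v(cnt.begin(), cnt.end());
  std::sort(v.begin(), v.end());
  CharacterVector grams(v.size());
  IntegerVector counts(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    grams[i] = decode_gram(v[i].first, q);
    counts[i] = v[i].second;
  }
  counts.attr("names") = grams;
  return List::create(_["q"] = q, _["counts"] = counts,
                      _["source_length"] = (int)s.size());
}

// [[Rcpp::export]]
int cpp_qgram_dist(std::string a, std::string b, int q) {
  std::unordered_map<int64_t, int> ca, cb;
  gram_counts(a, q, ca);
  gram_counts(b, q, cb);
  long d = 0;
  for (auto& kv : ca) {
    auto it = cb.find(kv.first);
    d += std::abs(kv.second - (it == cb.end() ? 0 : it->second));
  }
  for (auto& kv : cb)
    if (ca.find(kv.first) == ca.end()) d += kv.second;
  return (int)d;
}

// [[Rcpp::export]]
IntegerVector cpp_qgram_dist_many(std::string a, CharacterVector bs, int q) {
  std::unordered_map<int64_t, int> ca;
  gram_counts(a, q, ca);
  int n = bs.size();
  IntegerVector out(n);
  for (int k = 0; k < n; ++k) {
    std::string b = as<std::string>(bs[k]);
    std::unordered_map<int64_t, int> cb;
    gram_counts(b, q, cb);
    long d = 0;
    for (auto& kv : ca) {
      auto it = cb.find(kv.first);
      d += std::abs(kv.second - (it == cb.end() ? 0 : it->second));
    }
    for (auto& kv : cb)
      if (ca.find(kv.first) == ca.end()) d += kv.second;
    out[k] = (int)d;
  }
  return out;
}

// q-gram distance between `read` and every length-|read| window of `contig`,
// maintained incrementally as the window slides one position at a time.
// [[Rcpp::export]]
IntegerVector cpp_sliding_read_windows(std::string read, std::string contig,
                                       int q) {
  int nr = (int)read.size(), nc = (int)contig.size();
  if (nc < nr) return IntegerVector(0);
  DiffL1 st;
  {
    std::unordered_map<int64_t, int> cr;
    gram_counts(read, q, cr);
    for (auto& kv : cr) st.add(kv.first, kv.second);
  }
  int n_off = nc - nr + 1;
  IntegerVector out(n_off);
  // window [o, o + nr): grams start at o .. o + nr - q
  if (nr >= q)
    for (int p = 0; p <= nr - q; ++p) st.add(gram_at(contig, p, q), -1);
  out[0] = (int)st.l1;
  for (int o = 1; o < n_off; ++o) {
    if (nr >= q) {
      st.add(gram_at(contig, o - 1, q), +1);          // leaves on the left
      st.add(gram_at(contig, o + nr - q, q), -1);      // enters on the right
    }
    out[o] = (int)st.l1;
  }
  return out;
}

// Shift (diagonal) votes from exact shared seeds: every position pair where
// a length-`seed_len` substring of alpha matches one of beta votes for the
// shift alpha_pos - beta_pos.  Votes are smoothed over +-8 shifts (point
// mutations leave exact seeds; indels drift the diagonal slowly), and the
// top peaks are returned as equal-length overlap configurations.  This
// stays informative when q-gram count profiles have saturated, because a
// shared 12-mer at a consistent diagonal is vanishingly unlikely by chance.
// [[Rcpp::export]]
DataFrame cpp_diag_candidates(std::string alpha, std::string beta,
                              int seed_len, int min_overlap, int top_m) {
  int na = (int)alpha.size(), nb = (int)beta.size();
  std::vector<int> a_start, b_start, len_v, votes_v;
  if (na >= seed_len && nb >= seed_len && seed_len >= 1 && seed_len <= 27) {
    std::unordered_map<int64_t, std::vector<int>> idx;
    int64_t mod = pow5(seed_len - 1), val = 0;
    for (int i = 0; i < na; ++i) {
      if (i >= seed_len) val -= code5(alpha[i - seed_len]) * mod;
      val = val * 5 + code5(alpha[i]);
      if (i >= seed_len - 1) {
        auto& v = idx[val];
        if ((int)v.size() < 8) v.push_back(i - seed_len + 1);
      }
    }
    int n_shift = na + nb - 1;
    std::vector<int> votes((size_t)n_shift, 0);
    val = 0;
    for (int j = 0; j < nb; ++j) {
      if (j >= seed_len) val -= code5(beta[j - seed_len]) * mod;
      val = val * 5 + code5(beta[j]);
      if (j >= seed_len - 1) {
        auto it = idx.find(val);
        if (it != idx.end())
          for (int i : it->second)
            votes[(size_t)(i - (j - seed_len + 1) + nb - 1)]++;
      }
    }
    std::vector<long> sm((size_t)n_shift, 0);
    for (int s = 0; s < n_shift; ++s)
      for (int d = std::max(0, s - 8); d <= std::min(n_shift - 1, s + 8); ++d)
        sm[s] += votes[d];
    for (int pick = 0; pick < top_m; ++pick) {
      int bi = (int)(std::max_element(sm.begin(), sm.end()) - sm.begin());
      if (sm[bi] < 1) break;
      long v = sm[bi];
      for (int d = std::max(0, bi - 32);
           d <= std::min(n_shift - 1, bi + 32); ++d)
        sm[d] = 0;
      int s = bi - (nb - 1);  // beta start at alpha coordinate s
      int a0 = std::max(0, s), b0 = std::max(0, -s);
      int len = std::min(na, s + nb) - a0;
      if (len >= min_overlap) {
        a_start.push_back(a0);
        b_start.push_back(b0);
        len_v.push_back(len);
        votes_v.push_back((int)v);
      }
    }
  }
  return DataFrame::create(_["a_start"] = a_start, _["b_start"] = b_start,
                           _["len"] = len_v, _["votes"] = votes_v);
}

// All equal-length overlap configurations of alpha against beta with overlap
// length >= min_len, scored by the q-gram distance of the two overlap
// substrings, for every admissible q (overlap length in [4^(q-1), 4^(q+1)];
// q >= 2 with lengths < 4 falling back to q = 2).  Incremental updates: as
// the shift advances, each window boundary moves by at most one position.
// [[Rcpp::export]]
DataFrame cpp_sliding_overlaps(std::string alpha, std::string beta,
                               int min_len) {
  int na = (int)alpha.size(), nb = (int)beta.size();
  std::vector<int> a_start, b_start, len_v, q_v, dist_v;
  int maxov = std::min(na, nb);
  if (maxov >= min_len && min_len >= 1) {
    for (int q = 2; q == 2 || pow4l(q - 1) <= (long)maxov; ++q) {
      long lo = (q == 2) ? 1 : pow4l(q - 1);
      long hi = pow4l(q + 1);
      DiffL1 st;
      // shift s: beta's start sits at alpha coordinate s
      int a0 = 0, a1 = 0, b0 = nb, b1 = nb;  // state before first shift
      for (int s = -(nb - 1); s <= na - 1; ++s) {
        int na0 = std::max(0, s), na1 = std::min(na, s + nb);
        int nb0 = std::max(0, -s), nb1 = std::min(nb, na - s);
        // alpha window: grows at right, shrinks at left
        if (na1 > a1 && na1 - na0 >= q) st.add(gram_at(alpha, na1 - q, q), +1);
        if (na0 > a0 && a1 - a0 >= q) st.add(gram_at(alpha, a0, q), -1);
        // beta window: grows at left, shrinks at right
        if (nb0 < b0 && nb1 - nb0 >= q) st.add(gram_at(beta, nb0, q), -1);
        if (nb1 < b1 && b1 - b0 >= q) st.add(gram_at(beta, b1 - q, q), +1);
        a0 = na0; a1 = na1; b0 = nb0; b1 = nb1;
        int len = a1 - a0;
        if (len >= min_len &&
            ((len >= lo && len < hi) || (q == 2 && len < 4))) {
          a_start.push_back(a0);
          b_start.push_back(b0);
          len_v.push_back(len);
          q_v.push_back(q);
          dist_v.push_back((int)st.l1);
        }
      }
      if (q > 2 && pow4l(q) > (long)maxov) { /* next q has empty range */ }
    }
  }
  return DataFrame::create(_["a_start"] = a_start, _["b_start"] = b_start,
                           _["len"] = len_v, _["q"] = q_v,
                           _["dist"] = dist_v);
}
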