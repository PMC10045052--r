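#include <Rcpp.h>
#include "core.h"

using namespace Rcpp;
using namespace pasdist;

// [[Rcpp::export]]
int cpp_levenshtein(std::string x, std::string y) {
  return lev_exact(x, y);
}

// [[Rcpp::export]]
int cpp_levenshtein_banded(std::string x, std::string y, int bound) {
  return mg_core(x, y, 0, (long)bound);  // -1 marks EXCEEDS
}

// [[Rcpp::export]]
int cpp_margin_gap(std::string x, std::string y, int t) {
  return mg_core(x, y, t, -1);
}

// [[Rcpp::export]]
int cpp_margin_gap_bounded(std::string x, std::string y, int t, int bound) {
  return mg_core(x, y, t, (long)bound);
}

// Pairwise exact Levenshtein over a character vector (reference matrices).
// [[Rcpp::export]]
NumericMatrix cpp_lev_matrix(CharacterVector seqs) {
  int n = seqs.size();
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<std::string>(seqs[i]);
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double d = lev_exact(s[i], s[j]);
      out(i, j) = d;
      out(j, i) = d;
    }
  return out;
}
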