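#include <Rcpp.h>
#include <string>
#include <vector>

using namespace Rcpp;

// Needleman-Wunsch prefix score with Match = 1, Mismatch = 0, Indel = 0 and a
// zero boundary; equals the longest-common-subsequence length. Two-row DP.
static int nw_score_one(const std::string& a, const std::string& b) {
  const int n1 = a.size(), n2 = b.size();
  if (n1 == 0 || n2 == 0) return 0;
  std::vector<int> prev(n2 + 1, 0), cur(n2 + 1, 0);
  for (int p = 1; p <= n1; ++p) {
    const char ap = a[p - 1];
    for (int q = 1; q <= n2; ++q) {
      int diag = prev[q - 1] + (ap == b[q - 1] ? 1 : 0);
      int up = prev[q], left = cur[q - 1];
      int best = diag;
      if (up > best) best = up;
      if (left > best) best = left;
      cur[q] = best;
    }
    std::swap(prev, cur);
  }
  return prev[n2];
}

// [[Rcpp::export(name = ".nw_score_cpp")]]
IntegerVector nw_score_cpp(CharacterVector x, CharacterVector y) {
  const R_xlen_t n = x.size();
  if (y.size() != n) stop("x and y must have equal length");
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    out[i] = nw_score_one(as<std::string>(x[i]), as<std::string>(y[i]));
  }
  return out;
}

// All unordered pairwise similarities among equal-length sequences, returned
// as a symmetric matrix with unit diagonal. Backbone of the O(n^2 L^2)
// per-batch pair labeling.
// [[Rcpp::export(name = ".nw_sim_matrix_cpp")]]
NumericMatrix nw_sim_matrix_cpp(CharacterVector seqs) {
  const int n = seqs.size();
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<std::string>(seqs[i]);
  const double L = n > 0 ? (double)s[0].size() : 0.0;
  for (int i = 1; i < n; ++i)
    if ((double)s[i].size() != L) stop("all sequences must share one length");
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    out(i, i) = 1.0;
    for (int j = i + 1; j < n; ++j) {
      double sim = L > 0 ? nw_score_one(s[i], s[j]) / L : 1.0;
      out(i, j) = sim;
      out(j, i) = sim;
    }
  }
  return out;
}
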