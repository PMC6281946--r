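#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Weighted Levenshtein distance on integer-encoded token sequences.
// Codes are 1-based indices into the substitution-cost matrix; insertions
// and deletions always cost 1. With no cost matrix, substitution costs are
// 0/1 (classic Levenshtein). Two rolling rows keep memory at O(min side).
static double lev_core(const int* a, int m, const int* b, int n,
                       const NumericMatrix* cost) {
  std::vector<double> prev(n + 1), cur(n + 1);
  for (int j = 0; j <= n; ++j) prev[j] = j;
  for (int i = 1; i <= m; ++i) {
    cur[0] = i;
    const int ai = a[i - 1] - 1;
    for (int j = 1; j <= n; ++j) {
      const int bj = b[j - 1] - 1;
      double sub = cost ? (*cost)(ai, bj) : (ai == bj ? 0.0 : 1.0);
      double d = prev[j - 1] + sub;
      double del = prev[j] + 1.0;
      double ins = cur[j - 1] + 1.0;
      if (del < d) d = del;
      if (ins < d) d = ins;
      cur[j] = d;
    }
    prev.swap(cur);
  }
  return prev[n];
}

// [[Rcpp::export]]
double lev_dist_cpp(IntegerVector a, IntegerVector b,
                    Nullable<NumericMatrix> cost) {
  if (cost.isNotNull()) {
    NumericMatrix cm(cost);
    return lev_core(INTEGER(a), a.size(), INTEGER(b), b.size(), &cm);
  }
  return lev_core(INTEGER(a), a.size(), INTEGER(b), b.size(), nullptr);
}

// Full symmetric pairwise distance matrix over a list of encoded sequences.
// [[Rcpp::export]]
NumericMatrix lev_pairwise_cpp(List seqs, Nullable<NumericMatrix> cost) {
  const int n = seqs.size();
  NumericMatrix out(n, n);
  std::vector<IntegerVector> v;
  v.reserve(n);
  for (int i = 0; i < n; ++i) v.push_back(as<IntegerVector>(seqs[i]));
  NumericMatrix cm;
  bool weighted = cost.isNotNull();
  if (weighted) cm = NumericMatrix(cost);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d = lev_core(INTEGER(v[i]), v[i].size(),
                          INTEGER(v[j]), v[j].size(),
                          weighted ? &cm : nullptr);
      out(i, j) = d;
      out(j, i) = d;
    }
  }
  return out;
}
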