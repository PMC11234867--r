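#include <Rcpp.h>
using namespace Rcpp;

// Global alignment over a precomputed residue-residue similarity matrix with a
// flat per-position gap penalty (no extension term). Used by the iterative
// structure aligner, where S[i,j] = 1/(1 + (d_ij/d0)^2). Ties broken
// deterministically: diagonal, then gap-in-B (up), then gap-in-A (left).
// Returns the aligned index pairs (1-based) in increasing order.
// [[Rcpp::export(name = ".align_global_dp")]]
IntegerMatrix align_global_dp(NumericMatrix S, double gap) {
  const int n = S.nrow(), m = S.ncol();
  NumericMatrix F(n + 1, m + 1);
  IntegerMatrix ptr(n + 1, m + 1);  // 0 = diag, 1 = up, 2 = left

  for (int i = 1; i <= n; ++i) { F(i, 0) = F(i - 1, 0) - gap; ptr(i, 0) = 1; }
  for (int j = 1; j <= m; ++j) { F(0, j) = F(0, j - 1) - gap; ptr(0, j) = 2; }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double diag = F(i - 1, j - 1) + S(i - 1, j - 1);
      double up   = F(i - 1, j) - gap;
      double left = F(i, j - 1) - gap;
      double best = diag; int p = 0;
      if (up > best)   { best = up;   p = 1; }
      if (left > best) { best = left; p = 2; }
      F(i, j) = best;
      ptr(i, j) = p;
    }
  }

  // traceback
  std::vector<int> ai, bj;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int p = ptr(i, j);
    if (i > 0 && j > 0 && p == 0) {
      ai.push_back(i); bj.push_back(j);
      --i; --j;
    } else if (i > 0 && (p == 1 || j == 0)) {
      --i;
    } else {
      --j;
    }
  }
  const int k = (int) ai.size();
  IntegerMatrix out(k, 2);
  for (int r = 0; r < k; ++r) {
    out(r, 0) = ai[k - 1 - r];
    out(r, 1) = bj[k - 1 - r];
  }
  colnames(out) = CharacterVector::create("i", "j");
  return out;
}
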