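#include <Rcpp.h>
using namespace Rcpp;

// Takahashi (Erisman-Tinney) selected inverse of a sparse SPD matrix from
// its simplicial Cholesky factor C[p,p] = L L', followed by the trace
// tr(S C^-1). Entries of C^-1 are formed only on the filled pattern of L,
// which is closed under the index pairs the recurrence needs; S's pattern
// must be contained in C's.
//
// Lp, Li, Lx: CSC slots of the lower-triangular factor (rows sorted, the
// diagonal first in each column). perm: 0-based fill-reducing permutation.
// Si, Sj, Sx: triplets of S in original (unpermuted) indices, already
// offset into C's indexing.
// [[Rcpp::export(name = ".takahashi_trace")]]
double takahashi_trace(IntegerVector Lp, IntegerVector Li, NumericVector Lx,
                       IntegerVector perm, IntegerVector Si, IntegerVector Sj,
                       NumericVector Sx) {
  const int n = Lp.size() - 1;
  std::vector<double> Z((size_t)n * n, 0.0);
  std::vector<int> I;
  std::vector<double> l, zIj;
  for (int j = n - 1; j >= 0; --j) {
    const int k0 = Lp[j], k1 = Lp[j + 1];
    const double dLj = Lx[k0];          // diagonal entry of column j
    const int m = k1 - k0 - 1;
    if (Li[k0] != j) stop("factor column %d does not start at the diagonal", j + 1);
    if (m > 0) {
      I.resize(m); l.resize(m); zIj.assign(m, 0.0);
      for (int k = 0; k < m; ++k) {
        I[k] = Li[k0 + 1 + k];
        l[k] = Lx[k0 + 1 + k] / dLj;
      }
      // zIj = -(Z[I, I] %*% l)
      for (int b = 0; b < m; ++b) {
        const double lb = l[b];
        const double *col = &Z[(size_t)I[b] * n];
        for (int a = 0; a < m; ++a) zIj[a] -= col[I[a]] * lb;
      }
      double acc = 0.0;
      for (int a = 0; a < m; ++a) {
        Z[(size_t)j * n + I[a]] = zIj[a];
        Z[(size_t)I[a] * n + j] = zIj[a];
        acc += l[a] * zIj[a];
      }
      Z[(size_t)j * n + j] = 1.0 / (dLj * dLj) - acc;
    } else {
      Z[(size_t)j * n + j] = 1.0 / (dLj * dLj);
    }
  }
  std::vector<int> invp(n);
  for (int k = 0; k < n; ++k) invp[perm[k]] = k;
  double tr = 0.0;
  for (int t = 0; t < Si.size(); ++t) {
    const int a = invp[Si[t]], b = invp[Sj[t]];
    tr += Sx[t] * Z[(size_t)b * n + a];
  }
  return tr;
}
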