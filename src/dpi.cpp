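#include <Rcpp.h>
using namespace Rcpp;

// Data-processing-inequality marks on a dense weighted adjacency matrix.
// M is symmetric with M[i][j] > 0 iff the edge (i,j) exists (0 = absent).
// An edge (i,j) is marked for removal when some third node k forms a
// triangle with it (both (i,k) and (j,k) present) and
// M(i,j) < min(M(i,k), M(j,k)) - eps. All marks are computed on the input
// graph so removal is order-independent.
// [[Rcpp::export]]
LogicalMatrix dpi_marks(NumericMatrix M, double eps) {
  int n = M.nrow();
  if (M.ncol() != n) stop("adjacency matrix must be square");
  LogicalMatrix drop(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double mij = M(i, j);
      if (mij <= 0) continue;
      bool rem = false;
      for (int k = 0; k < n; ++k) {
        if (k == i || k == j) continue;
        double mik = M(i, k);
        if (mik <= 0) continue;
        double mjk = M(j, k);
        if (mjk <= 0) continue;
        double lo = mik < mjk ? mik : mjk;
        if (mij < lo - eps) { rem = true; break; }
      }
      drop(i, j) = rem;
      drop(j, i) = rem;
    }
  }
  return drop;
}
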