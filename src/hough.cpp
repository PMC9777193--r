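#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Generalized-Hough vote accumulation for one (scale, rotation) cell.
//
// The score of an accumulator cell is the number of rasterized template
// offsets t for which at least one edge pixel lies within `tol` pixels
// (Chebyshev) of cell_center + t; equivalently, in the dual direction used
// here, a template point votes for a cell at most once however many edge
// pixels support it. Scores are therefore bounded by the template size and
// measure the matched fraction of the border template. Cells sit at
// (row0 + i*stride, col0 + j*stride), i in [0, n_rows), j in [0, n_cols).
// The +/- tol band stands in for rasterizing the template with unit
// thickness. Deterministic; ties are resolved by the caller.

static inline int floordiv(int a, int b) {
  int q = a / b;
  if ((a % b != 0) && ((a < 0) != (b < 0))) --q;
  return q;
}
static inline int ceildiv(int a, int b) { return -floordiv(-a, b); }

// [[Rcpp::export]]
IntegerMatrix hough_vote_cpp(IntegerVector edge_row, IntegerVector edge_col,
                             IntegerVector off_row, IntegerVector off_col,
                             int row0, int col0, int stride,
                             int n_rows, int n_cols, int tol) {
  const int ne = edge_row.size(), nt = off_row.size();
  IntegerMatrix acc(n_rows, n_cols);
  std::vector<int> seen((size_t)n_rows * n_cols, -1);
  for (int t = 0; t < nt; ++t) {
    const int tr = off_row[t], tc = off_col[t];
    for (int e = 0; e < ne; ++e) {
      const int cr = edge_row[e] - tr;
      const int cc = edge_col[e] - tc;
      int ilo = ceildiv(cr - tol - row0, stride);
      int ihi = floordiv(cr + tol - row0, stride);
      int jlo = ceildiv(cc - tol - col0, stride);
      int jhi = floordiv(cc + tol - col0, stride);
      if (ilo < 0) ilo = 0;
      if (jlo < 0) jlo = 0;
      if (ihi > n_rows - 1) ihi = n_rows - 1;
      if (jhi > n_cols - 1) jhi = n_cols - 1;
      for (int j = jlo; j <= jhi; ++j) {
        for (int i = ilo; i <= ihi; ++i) {
          size_t idx = (size_t)j * n_rows + i;
          if (seen[idx] != t) {
            seen[idx] = t;
            acc(i, j) += 1;
          }
        }
      }
    }
  }
  return acc;
}
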