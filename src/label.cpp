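#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 8-connected component labeling by breadth-first flood fill.
// Labels are assigned in column-major scan order, starting at 1.

// [[Rcpp::export]]
IntegerMatrix label8_cpp(LogicalMatrix m) {
  const int nr = m.nrow(), nc = m.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> queue;
  queue.reserve(256);
  int next = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!m(i, j) || lab(i, j)) continue;
      ++next;
      lab(i, j) = next;
      queue.clear();
      queue.push_back(j * nr + i);
      while (!queue.empty()) {
        int idx = queue.back();
        queue.pop_back();
        int ci = idx % nr, cj = idx / nr;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj) continue;
            int ni = ci + di, nj = cj + dj;
            if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
            if (m(ni, nj) && !lab(ni, nj)) {
              lab(ni, nj) = next;
              queue.push_back(nj * nr + ni);
            }
          }
        }
      }
    }
  }
  return lab;
}
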