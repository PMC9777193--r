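#include <Rcpp.h>
using namespace Rcpp;

// Zhang-Suen morphological thinning to a 1-pixel-wide 8-connected skeleton.
// Two-subiteration scheme; repeats until stable. The input border is treated
// as background via an internal 1-pixel pad.

// [[Rcpp::export]]
LogicalMatrix zs_thin(LogicalMatrix m) {
  const int nr = m.nrow(), nc = m.ncol();
  const int H = nr + 2, W = nc + 2;
  std::vector<unsigned char> img((size_t)H * W, 0);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      img[(size_t)(j + 1) * H + (i + 1)] = m(i, j) ? 1 : 0;

  std::vector<size_t> kill;
  kill.reserve(1024);
  bool changed = true;
  while (changed) {
    changed = false;
    for (int phase = 0; phase < 2; ++phase) {
      kill.clear();
      for (int j = 1; j <= nc; ++j) {
        for (int i = 1; i <= nr; ++i) {
          size_t idx = (size_t)j * H + i;
          if (!img[idx]) continue;
          // neighbors clockwise from north: p2..p9
          int p2 = img[idx - 1];
          int p3 = img[idx + H - 1];
          int p4 = img[idx + H];
          int p5 = img[idx + H + 1];
          int p6 = img[idx + 1];
          int p7 = img[idx - H + 1];
          int p8 = img[idx - H];
          int p9 = img[idx - H - 1];
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                  (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                  (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (A != 1) continue;
          bool ok;
          if (phase == 0)
            ok = (p2 * p4 * p6 == 0) && (p4 * p6 * p8 == 0);
          else
            ok = (p2 * p4 * p8 == 0) && (p2 * p6 * p8 == 0);
          if (ok) kill.push_back(idx);
        }
      }
      if (!kill.empty()) {
        changed = true;
        for (size_t k = 0; k < kill.size(); ++k) img[kill[k]] = 0;
      }
    }
  }

  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out(i, j) = img[(size_t)(j + 1) * H + (i + 1)] != 0;
  return out;
}
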