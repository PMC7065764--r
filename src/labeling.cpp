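#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labeling of a 0/1 grid by flood fill.
// Pixels are scanned row-major, so patch ids are assigned in raster order
// of each patch's first pixel; connectivity is 4 or 8.
// [[Rcpp::export(name = ".ccLabel")]]
IntegerMatrix ccLabel(const IntegerMatrix& grid, int connectivity) {
  const int nr = grid.nrow(), nc = grid.ncol();
  IntegerMatrix labels(nr, nc);
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 0, 0, 1};
  const int dc4[4] = {0, -1, 1, 0};
  const int* dr = (connectivity == 8) ? dr8 : dr4;
  const int* dc = (connectivity == 8) ? dc8 : dc4;
  const int nn = (connectivity == 8) ? 8 : 4;
  int next = 0;
  std::vector<int> stack;
  stack.reserve(1024);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (grid(r, c) != 1 || labels(r, c) != 0) continue;
      ++next;
      labels(r, c) = next;
      stack.push_back(r * nc + c);
      while (!stack.empty()) {
        int p = stack.back();
        stack.pop_back();
        int pr = p / nc, pc = p % nc;
        for (int i = 0; i < nn; ++i) {
          int qr = pr + dr[i], qc = pc + dc[i];
          if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
          if (grid(qr, qc) == 1 && labels(qr, qc) == 0) {
            labels(qr, qc) = next;
            stack.push_back(qr * nc + qc);
          }
        }
      }
    }
  }
  return labels;
}
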