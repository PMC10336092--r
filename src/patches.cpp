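#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Connected-component labeling of a binary lattice.
// Pixels equal to 1 are foreground; 0 and NA are background.
// Labels are assigned in row-major order of each component's first pixel
// (scanning from the top-left), so the labeling is deterministic.
// connectivity: 4 (rook) or 8 (queen).
// [[Rcpp::export]]
IntegerMatrix label_patches_cpp(const IntegerMatrix m, const int connectivity) {
  const int nr = m.nrow(), nc = m.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);

  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 0, 0, 1};
  const int dc4[4] = {0, -1, 1, 0};
  const int *dr = (connectivity == 8) ? dr8 : dr4;
  const int *dc = (connectivity == 8) ? dc8 : dc4;
  const int nd = (connectivity == 8) ? 8 : 4;

  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      if (m(i, j) == 1 && lab(i, j) == 0) {  // NA_INTEGER != 1
        ++next;
        lab(i, j) = next;
        q.push(std::make_pair(i, j));
        while (!q.empty()) {
          std::pair<int, int> p = q.front();
          q.pop();
          for (int k = 0; k < nd; ++k) {
            int r = p.first + dr[k], c = p.second + dc[k];
            if (r < 0 || r >= nr || c < 0 || c >= nc) continue;
            if (lab(r, c) == 0 && m(r, c) == 1) {
              lab(r, c) = next;
              q.push(std::make_pair(r, c));
            }
          }
        }
      }
    }
  }
  return lab;
}

// Edge adjacency counts for a binary lattice.
// Returns c(internal, boundary):
//   internal = number of 4-neighbour pixel pairs with one forest (1) and one
//              non-forest (0) pixel; pairs involving NA are not counted.
//   boundary = number of window-border sides of forest pixels (a corner
//              forest pixel contributes two sides).
// [[Rcpp::export]]
IntegerVector edge_adjacency_cpp(const IntegerMatrix m) {
  const int nr = m.nrow(), nc = m.ncol();
  long internal = 0, boundary = 0;
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      const int v = m(i, j);
      if (v == 1) {
        if (i == 0) ++boundary;
        if (i == nr - 1) ++boundary;
        if (j == 0) ++boundary;
        if (j == nc - 1) ++boundary;
      }
      if (v == NA_INTEGER) continue;
      // right and down neighbours only, so each pair is counted once
      if (i + 1 < nr) {
        const int w = m(i + 1, j);
        if (w != NA_INTEGER && v + w == 1) ++internal;
      }
      if (j + 1 < nc) {
        const int w = m(i, j + 1);
        if (w != NA_INTEGER && v + w == 1) ++internal;
      }
    }
  }
  return IntegerVector::create(internal, boundary);
}
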