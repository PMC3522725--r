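#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Binary dilation with an arbitrary structuring element given as a two-column
// matrix of (row, col) offsets. Out-of-frame neighbours are ignored.
// [[Rcpp::export]]
LogicalMatrix cpp_dilate(const LogicalMatrix& m, const IntegerMatrix& offsets) {
  const int nr = m.nrow(), nc = m.ncol(), no = offsets.nrow();
  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!m(i, j)) continue;
      for (int o = 0; o < no; ++o) {
        const int ii = i + offsets(o, 0), jj = j + offsets(o, 1);
        if (ii >= 0 && ii < nr && jj >= 0 && jj < nc) out(ii, jj) = true;
      }
    }
  }
  return out;
}

// Binary erosion: pixel survives iff every structuring-element neighbour is
// set. pad_foreground controls the out-of-frame convention: false (plain
// erosion, zero padding, the border erodes) or true (used inside closing so
// that closing stays extensive at the frame border).
// [[Rcpp::export]]
LogicalMatrix cpp_erode(const LogicalMatrix& m, const IntegerMatrix& offsets,
                        const bool pad_foreground = false) {
  const int nr = m.nrow(), nc = m.ncol(), no = offsets.nrow();
  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!m(i, j)) continue;
      bool keep = true;
      for (int o = 0; o < no && keep; ++o) {
        const int ii = i + offsets(o, 0), jj = j + offsets(o, 1);
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) {
          if (!pad_foreground) keep = false;
        } else if (!m(ii, jj)) keep = false;
      }
      out(i, j) = keep;
    }
  }
  return out;
}

// Fill holes: background regions (4-connected) not reachable from the frame
// border become foreground.
// [[Rcpp::export]]
LogicalMatrix cpp_fill_holes(const LogicalMatrix& m) {
  const int nr = m.nrow(), nc = m.ncol();
  std::vector<char> reach(static_cast<size_t>(nr) * nc, 0);
  std::queue<std::pair<int, int> > q;
  auto push = [&](int i, int j) {
    if (i < 0 || i >= nr || j < 0 || j >= nc) return;
    const size_t idx = static_cast<size_t>(j) * nr + i;
    if (reach[idx] || m(i, j)) return;
    reach[idx] = 1;
    q.push(std::make_pair(i, j));
  };
  for (int i = 0; i < nr; ++i) { push(i, 0); push(i, nc - 1); }
  for (int j = 0; j < nc; ++j) { push(0, j); push(nr - 1, j); }
  while (!q.empty()) {
    const int i = q.front().first, j = q.front().second;
    q.pop();
    push(i - 1, j); push(i + 1, j); push(i, j - 1); push(i, j + 1);
  }
  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out(i, j) = m(i, j) || !reach[static_cast<size_t>(j) * nr + i];
  return out;
}

// Connected-component labelling (8-connectivity, ImageJ-style), labels 1..n
// in scan order; 0 is background.
// [[Rcpp::export]]
IntegerMatrix cpp_label(const LogicalMatrix& m) {
  const int nr = m.nrow(), nc = m.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!m(i, j) || lab(i, j)) continue;
      lab(i, j) = ++next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        const int ci = q.front().first, cj = q.front().second;
        q.pop();
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            const int ii = ci + di, jj = cj + dj;
            if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
            if (m(ii, jj) && !lab(ii, jj)) {
              lab(ii, jj) = next;
              q.push(std::make_pair(ii, jj));
            }
          }
        }
      }
    }
  }
  return lab;
}
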