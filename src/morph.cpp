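#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// offsets: k x 2 integer matrix of (dr, dc) positions of the structuring
// element's active cells relative to its centre. Outside the image is
// treated as background.

// [[Rcpp::export]]
LogicalMatrix cpp_dilate(LogicalMatrix mask, IntegerMatrix offsets) {
  const int nr = mask.nrow(), nc = mask.ncol(), k = offsets.nrow();
  LogicalMatrix out(nr, nc);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      if (!mask(r, c)) continue;
      for (int o = 0; o < k; ++o) {
        int rr = r + offsets(o, 0), cc = c + offsets(o, 1);
        if (rr >= 0 && rr < nr && cc >= 0 && cc < nc) out(rr, cc) = true;
      }
    }
  return out;
}

// [[Rcpp::export]]
LogicalMatrix cpp_erode(LogicalMatrix mask, IntegerMatrix offsets) {
  const int nr = mask.nrow(), nc = mask.ncol(), k = offsets.nrow();
  LogicalMatrix out(nr, nc);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      bool all = true;
      for (int o = 0; o < k && all; ++o) {
        int rr = r + offsets(o, 0), cc = c + offsets(o, 1);
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc || !mask(rr, cc))
          all = false;
      }
      out(r, c) = all;
    }
  return out;
}

// Fixpoint of X_k = (X_{k-1} (+) e) /\ allowed started from the border
// cells of `allowed`; equals BFS reachability over the SE offsets when the
// SE contains its centre (both shipped SEs do).
// [[Rcpp::export]]
LogicalMatrix cpp_border_reach(LogicalMatrix allowed, IntegerMatrix offsets) {
  const int nr = allowed.nrow(), nc = allowed.ncol(), k = offsets.nrow();
  LogicalMatrix vis(nr, nc);
  std::queue<std::pair<int, int> > q;
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c)
      if ((r == 0 || r == nr - 1 || c == 0 || c == nc - 1) && allowed(r, c) &&
          !vis(r, c)) {
        vis(r, c) = true;
        q.push(std::make_pair(r, c));
      }
  while (!q.empty()) {
    std::pair<int, int> p = q.front();
    q.pop();
    for (int o = 0; o < k; ++o) {
      int rr = p.first + offsets(o, 0), cc = p.second + offsets(o, 1);
      if (rr >= 0 && rr < nr && cc >= 0 && cc < nc && allowed(rr, cc) &&
          !vis(rr, cc)) {
        vis(rr, cc) = true;
        q.push(std::make_pair(rr, cc));
      }
    }
  }
  return vis;
}

// Connected-component labelling (connectivity 4 or 8).
// [[Rcpp::export]]
IntegerMatrix cpp_label(LogicalMatrix mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 0, 0, 1};
  const int dc4[4] = {0, -1, 1, 0};
  const int *dr = connectivity == 8 ? dr8 : dr4;
  const int *dc = connectivity == 8 ? dc8 : dc4;
  const int nn = connectivity == 8 ? 8 : 4;
  std::queue<std::pair<int, int> > q;
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      lab(r, c) = ++next;
      q.push(std::make_pair(r, c));
      while (!q.empty()) {
        std::pair<int, int> p = q.front();
        q.pop();
        for (int o = 0; o < nn; ++o) {
          int rr = p.first + dr[o], cc = p.second + dc[o];
          if (rr >= 0 && rr < nr && cc >= 0 && cc < nc && mask(rr, cc) &&
              lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            q.push(std::make_pair(rr, cc));
          }
        }
      }
    }
  return lab;
}
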