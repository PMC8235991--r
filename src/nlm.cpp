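#include <Rcpp.h>
using namespace Rcpp;

// Symmetric (half-sample) reflection of an index into [0, n-1].
static inline int reflect_idx(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Gaussian-weighted squared patch distance between patches centred at
// (r1,c1) and (r2,c2); kernel is the (2s+1)x(2s+1) normalised weight grid.
// Borders are handled by symmetric reflection.
static double patch_dist(const NumericMatrix &img, int r1, int c1,
                         int r2, int c2, const NumericMatrix &kernel,
                         int sim_r) {
  const int nr = img.nrow(), nc = img.ncol();
  double d = 0.0;
  for (int dr = -sim_r; dr <= sim_r; ++dr) {
    for (int dc = -sim_r; dc <= sim_r; ++dc) {
      double a = img(reflect_idx(r1 + dr, nr), reflect_idx(c1 + dc, nc));
      double b = img(reflect_idx(r2 + dr, nr), reflect_idx(c2 + dc, nc));
      double diff = a - b;
      d += kernel(dr + sim_r, dc + sim_r) * diff * diff;
    }
  }
  return d;
}

// [[Rcpp::export]]
double cpp_patch_distance(NumericMatrix img, int r1, int c1, int r2, int c2,
                          NumericMatrix kernel, int sim_r) {
  return patch_dist(img, r1 - 1, c1 - 1, r2 - 1, c2 - 1, kernel, sim_r);
}

// Non-local means: each output pixel is the weight-normalised average of
// candidate pixels inside the clipped search window, weights
// exp(-d/h^2) with d the Gaussian-weighted patch distance. The image is
// reflect-padded by sim_r once so the patch loop needs no bound checks.
// [[Rcpp::export]]
NumericMatrix cpp_nlm(NumericMatrix img, double h, int search_r, int sim_r,
                      NumericMatrix kernel) {
  const int nr = img.nrow(), nc = img.ncol();
  const int pr = nr + 2 * sim_r, pc = nc + 2 * sim_r;
  const int side = 2 * sim_r + 1;
  std::vector<double> pad((size_t)pr * pc);
  for (int c = 0; c < pc; ++c) {
    int sc = reflect_idx(c - sim_r, nc);
    for (int r = 0; r < pr; ++r)
      pad[(size_t)c * pr + r] = img(reflect_idx(r - sim_r, nr), sc);
  }
  std::vector<double> kw((size_t)side * side);
  for (int dc = 0; dc < side; ++dc)
    for (int dr = 0; dr < side; ++dr)
      kw[(size_t)dc * side + dr] = kernel(dr, dc);

  NumericMatrix out(nr, nc);
  const double h2 = h * h;
  for (int c = 0; c < nc; ++c) {
    const int c_lo = std::max(0, c - search_r), c_hi = std::min(nc - 1, c + search_r);
    for (int r = 0; r < nr; ++r) {
      const int r_lo = std::max(0, r - search_r), r_hi = std::min(nr - 1, r + search_r);
      double z = 0.0, acc = 0.0;
      const double *p1 = &pad[(size_t)c * pr + r];  // patch origin (top-left)
      for (int c2 = c_lo; c2 <= c_hi; ++c2) {
        for (int r2 = r_lo; r2 <= r_hi; ++r2) {
          const double *p2 = &pad[(size_t)c2 * pr + r2];
          double d = 0.0;
          for (int dc = 0; dc < side; ++dc) {
            const double *a = p1 + (size_t)dc * pr;
            const double *b = p2 + (size_t)dc * pr;
            const double *k = &kw[(size_t)dc * side];
            for (int dr = 0; dr < side; ++dr) {
              double diff = a[dr] - b[dr];
              d += k[dr] * diff * diff;
            }
          }
          double w = std::exp(-d / h2);
          z += w;
          acc += w * pad[(size_t)(c2 + sim_r) * pr + r2 + sim_r];
        }
      }
      out(r, c) = acc / z;
    }
  }
  return out;
}
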