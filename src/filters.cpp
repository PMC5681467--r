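#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// reflect-with-edge-duplication boundary: ... c b a | a b c ... | c b a
static inline int reflect_index(int p, int n) {
  if (n == 1) return 0;
  while (p < 0 || p >= n) {
    if (p < 0) p = -1 - p;
    if (p >= n) p = 2 * n - 1 - p;
  }
  return p;
}

// Separable 2D correlation with reflected boundaries. Kernels are centred
// (odd length); slice is a ny x nx matrix indexed (y, x), column-major.
// [[Rcpp::export]]
NumericMatrix cpp_sep_conv2(const NumericMatrix& slice,
                            const NumericVector& kernel_y,
                            const NumericVector& kernel_x) {
  const int ny = slice.nrow(), nx = slice.ncol();
  const int ly = kernel_y.size(), lx = kernel_x.size();
  const int cy = (ly - 1) / 2, cx = (lx - 1) / 2;
  NumericMatrix tmp(ny, nx), out(ny, nx);
  // along y (rows within each column)
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      double acc = 0.0;
      for (int t = 0; t < ly; ++t)
        acc += kernel_y[t] * slice(reflect_index(y + t - cy, ny), x);
      tmp(y, x) = acc;
    }
  }
  // along x
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      double acc = 0.0;
      for (int t = 0; t < lx; ++t)
        acc += kernel_x[t] * tmp(y, reflect_index(x + t - cx, nx));
      out(y, x) = acc;
    }
  }
  return out;
}

// Per-pixel Shannon entropy (base 2) of the intensity histogram over a disc
// window, intensities quantised to `bins` equal-width bins over [lo, hi].
// [[Rcpp::export]]
NumericMatrix cpp_entropy2d(const NumericMatrix& slice, int radius, int bins,
                            double lo, double hi) {
  const int ny = slice.nrow(), nx = slice.ncol();
  NumericMatrix out(ny, nx);
  if (hi <= lo) return out;  // degenerate range: entropy 0 everywhere

  // quantise once
  IntegerMatrix q(ny, nx);
  const double scale = bins / (hi - lo);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      int b = (int)std::floor((slice(y, x) - lo) * scale);
      if (b < 0) b = 0;
      if (b >= bins) b = bins - 1;
      q(y, x) = b;
    }

  // disc offsets
  std::vector<int> dy, dx;
  for (int a = -radius; a <= radius; ++a)
    for (int b = -radius; b <= radius; ++b)
      if (a * a + b * b <= radius * radius) { dy.push_back(a); dx.push_back(b); }
  const int m = (int)dy.size();

  std::vector<int> hist(bins);
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      std::fill(hist.begin(), hist.end(), 0);
      for (int t = 0; t < m; ++t)
        ++hist[q(reflect_index(y + dy[t], ny), reflect_index(x + dx[t], nx))];
      double h = 0.0;
      for (int b = 0; b < bins; ++b)
        if (hist[b] > 0) {
          double p = (double)hist[b] / m;
          h -= p * std::log2(p);
        }
      out(y, x) = h;
    }
  }
  return out;
}

// 3D connected-component labelling of a 0/1 volume with 6 or 26 connectivity.
// dims = (nz, ny, nx); the array is column-major with z fastest, matching an
// R array of dim c(nz, ny, nx). Labels are 1..N, assigned in scan order of
// the linear index (z fastest, then y, then x).
// [[Rcpp::export]]
IntegerVector cpp_label3d(const IntegerVector& mask, const IntegerVector& dims,
                          int connectivity) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(n);

  std::vector<std::array<int, 3>> nb;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dz == 0 && dy == 0 && dx == 0) continue;
        int manh = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (connectivity == 6 && manh > 1) continue;
        nb.push_back({dz, dy, dx});
      }

  int next = 0;
  std::queue<R_xlen_t> qq;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (mask[i] == 0 || lab[i] != 0) continue;
    lab[i] = ++next;
    qq.push(i);
    while (!qq.empty()) {
      R_xlen_t cur = qq.front(); qq.pop();
      int z = (int)(cur % nz);
      int y = (int)((cur / nz) % ny);
      int x = (int)(cur / ((R_xlen_t)nz * ny));
      for (size_t t = 0; t < nb.size(); ++t) {
        int zz = z + nb[t][0], yy = y + nb[t][1], xx = x + nb[t][2];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
          continue;
        R_xlen_t j = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
        if (mask[j] != 0 && lab[j] == 0) { lab[j] = next; qq.push(j); }
      }
    }
  }
  lab.attr("n_labels") = next;
  return lab;
}
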