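#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Neighbor offsets for 6/18/26 connectivity on a (z, y, x) grid.
static std::vector<std::array<int,3>> neighbor_offsets(int connectivity) {
  std::vector<std::array<int,3>> off;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int m = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (m == 0) continue;
        if (connectivity == 6  && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        off.push_back({dz, dy, dx});
      }
  return off;
}

// 3D connected-component labeling by breadth-first search.
// Labels are contiguous from 1, assigned in raster-scan order of the
// first-encountered voxel (column-major linear index order: z fastest,
// then y, then x).
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dim, int connectivity) {
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (mask.size() != n) stop("mask length does not match dim");
  IntegerVector labels(n, 0);
  std::vector<std::array<int,3>> off = neighbor_offsets(connectivity);
  int next_label = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || labels[i] != 0) continue;
    labels[i] = ++next_label;
    q.push(i);
    while (!q.empty()) {
      R_xlen_t cur = q.front(); q.pop();
      int z = (int)(cur % nz);
      int y = (int)((cur / nz) % ny);
      int x = (int)(cur / ((R_xlen_t)nz * ny));
      for (size_t k = 0; k < off.size(); ++k) {
        int zz = z + off[k][0], yy = y + off[k][1], xx = x + off[k][2];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
        R_xlen_t j = (R_xlen_t)xx * nz * ny + (R_xlen_t)yy * nz + zz;
        if (mask[j] && labels[j] == 0) { labels[j] = next_label; q.push(j); }
      }
    }
  }
  labels.attr("dim") = dim;
  return labels;
}

// Convolve along one axis with a symmetric kernel, replicating edges.
static void conv_axis(std::vector<double>& a, std::vector<double>& tmp,
                      int nz, int ny, int nx, int axis,
                      const std::vector<double>& kern) {
  int r = ((int)kern.size() - 1) / 2;
  int len   = (axis == 0) ? nz : (axis == 1) ? ny : nx;
  R_xlen_t stride = (axis == 0) ? 1 : (axis == 1) ? nz : (R_xlen_t)nz * ny;
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  for (R_xlen_t i = 0; i < n; ++i) {
    int pos;
    if (axis == 0) pos = (int)(i % nz);
    else if (axis == 1) pos = (int)((i / nz) % ny);
    else pos = (int)(i / ((R_xlen_t)nz * ny));
    double acc = 0.0;
    for (int k = -r; k <= r; ++k) {
      int p = pos + k;
      if (p < 0) p = 0;
      if (p >= len) p = len - 1;
      acc += kern[k + r] * a[i + (R_xlen_t)(p - pos) * stride];
    }
    tmp[i] = acc;
  }
  a.swap(tmp);
}

static std::vector<double> gauss_kernel(double sigma) {
  int r = std::max(1, (int)std::ceil(4.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (auto& v : k) v /= s;
  return k;
}

// Separable Gaussian blur of a (z, y, x) volume; sigmas in voxel units.
// A sigma of 0 skips that axis. Edges are replicated.
// [[Rcpp::export]]
NumericVector cpp_blur3d(NumericVector img, IntegerVector dim,
                         double sigma_z, double sigma_y, double sigma_x) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (img.size() != n) stop("image length does not match dim");
  std::vector<double> a(img.begin(), img.end()), tmp(n);
  if (sigma_z > 0) conv_axis(a, tmp, nz, ny, nx, 0, gauss_kernel(sigma_z));
  if (sigma_y > 0) conv_axis(a, tmp, nz, ny, nx, 1, gauss_kernel(sigma_y));
  if (sigma_x > 0) conv_axis(a, tmp, nz, ny, nx, 2, gauss_kernel(sigma_x));
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dim;
  return out;
}
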