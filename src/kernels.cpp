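#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Trilinear sampling of a 3-D array at fractional 0-based voxel coordinates.
// outside == 0: points outside the grid sample as `fill`;
// outside == 1: coordinates are clamped to the edge (replicate boundary).
// [[Rcpp::export]]
NumericVector cpp_sample_trilinear(NumericVector arr, IntegerVector dim,
                                   NumericMatrix pts, int outside,
                                   double fill) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = pts.nrow();
  NumericVector out(n);
  const double *a = arr.begin();
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  for (int p = 0; p < n; ++p) {
    double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    if (outside == 1) {
      x = std::min(std::max(x, 0.0), (double)(nx - 1));
      y = std::min(std::max(y, 0.0), (double)(ny - 1));
      z = std::min(std::max(z, 0.0), (double)(nz - 1));
    } else if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 ||
               z > nz - 1) {
      out[p] = fill;
      continue;
    }
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y),
        k0 = (int)std::floor(z);
    if (i0 > nx - 2) i0 = nx - 2;
    if (j0 > ny - 2) j0 = ny - 2;
    if (k0 > nz - 2) k0 = nz - 2;
    if (i0 < 0) i0 = 0;
    if (j0 < 0) j0 = 0;
    if (k0 < 0) k0 = 0;
    double fx = x - i0, fy = y - j0, fz = z - k0;
    const double *base = a + i0 * sx + j0 * sy + k0 * sz;
    double c000 = base[0], c100 = base[sx];
    double c010 = base[sy], c110 = base[sx + sy];
    double c001 = base[sz], c101 = base[sx + sz];
    double c011 = base[sy + sz], c111 = base[sx + sy + sz];
    double c00 = c000 * (1 - fx) + c100 * fx;
    double c10 = c010 * (1 - fx) + c110 * fx;
    double c01 = c001 * (1 - fx) + c101 * fx;
    double c11 = c011 * (1 - fx) + c111 * fx;
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    out[p] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}

// Nearest-neighbour sampling (used for label volumes). Outside -> fill.
// [[Rcpp::export]]
NumericVector cpp_sample_nearest(NumericVector arr, IntegerVector dim,
                                 NumericMatrix pts, double fill) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = pts.nrow();
  NumericVector out(n);
  const double *a = arr.begin();
  const R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;
  for (int p = 0; p < n; ++p) {
    int i = (int)std::floor(pts(p, 0) + 0.5);
    int j = (int)std::floor(pts(p, 1) + 0.5);
    int k = (int)std::floor(pts(p, 2) + 0.5);
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) {
      out[p] = fill;
    } else {
      out[p] = a[i + j * sy + k * sz];
    }
  }
  return out;
}

static void gauss_kernel(double sigma, std::vector<double> &w) {
  int r = (int)std::ceil(4.0 * sigma);
  if (r < 1) r = 1;
  w.assign(2 * r + 1, 0.0);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    double v = std::exp(-0.5 * (i * i) / (sigma * sigma));
    w[i + r] = v;
    s += v;
  }
  for (size_t i = 0; i < w.size(); ++i) w[i] /= s;
}

// Separable Gaussian smoothing of a 3-D array with per-axis sigma in voxel
// units; replicate-edge boundary handling. sigma <= 0 skips that axis.
// [[Rcpp::export]]
NumericVector cpp_gauss_smooth3d(NumericVector arr, IntegerVector dim,
                                 NumericVector sigma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  std::vector<double> buf(arr.begin(), arr.end());
  std::vector<double> tmp(nvox);
  const int n_ax[3] = {nx, ny, nz};
  const R_xlen_t stride_ax[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 0) continue;
    std::vector<double> w;
    gauss_kernel(s, w);
    const int r = ((int)w.size() - 1) / 2;
    const int n = n_ax[ax];
    const R_xlen_t stride = stride_ax[ax];
    const R_xlen_t nlines = nvox / n;
    // iterate over all lines along this axis
    for (R_xlen_t line = 0; line < nlines; ++line) {
      // compute base offset of this line
      R_xlen_t base;
      if (ax == 0) {
        base = line * nx;
      } else if (ax == 1) {
        R_xlen_t i = line % nx, k = line / nx;
        base = i + k * (R_xlen_t)nx * ny;
      } else {
        base = line;  // line indexes (i,j) plane directly
      }
      for (int p = 0; p < n; ++p) {
        double acc = 0.0;
        for (int q = -r; q <= r; ++q) {
          int pp = p + q;
          if (pp < 0) pp = 0;
          if (pp >= n) pp = n - 1;
          acc += w[q + r] * buf[base + pp * stride];
        }
        tmp[base + p * stride] = acc;
      }
    }
    buf.swap(tmp);
  }
  NumericVector out(buf.begin(), buf.end());
  out.attr("dim") = dim;
  return out;
}

// Per-voxel modal label over a stack of label volumes, ties broken by the
// smallest label value. `stack` is nvox x m; `labels` the sorted candidate
// label values.
// [[Rcpp::export]]
IntegerVector cpp_voxel_vote(IntegerMatrix stack, IntegerVector labels) {
  const int nvox = stack.nrow(), m = stack.ncol(), nl = labels.size();
  IntegerVector out(nvox);
  std::vector<int> counts(nl);
  // map label value -> index (labels are small non-negative ints)
  int maxlab = 0;
  for (int l = 0; l < nl; ++l)
    if (labels[l] > maxlab) maxlab = labels[l];
  std::vector<int> idx(maxlab + 1, -1);
  for (int l = 0; l < nl; ++l) idx[labels[l]] = l;
  for (int v = 0; v < nvox; ++v) {
    std::fill(counts.begin(), counts.end(), 0);
    for (int j = 0; j < m; ++j) counts[idx[stack(v, j)]]++;
    int best = 0;  // labels sorted ascending: first strict max wins ties
    for (int l = 1; l < nl; ++l)
      if (counts[l] > counts[best]) best = l;
    out[v] = labels[best];
  }
  return out;
}
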