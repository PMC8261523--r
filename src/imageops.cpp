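#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Rasterize Gaussian-profile tubes into a volume by maximum compositing.
// points: n x 4 matrix (x, y, z, sigma) of densely resampled centerline
// samples in micrometres; voxel centers sit at (i-1)*d, i = 1..n (0-based
// physical origin). Amplitude of a sample at distance d is exp(-d^2/(2 s^2));
// the volume keeps the per-voxel maximum over all samples, so overlapping
// vessels stay in [0, 1].
// [[Rcpp::export]]
NumericVector cpp_render_tubes(NumericVector vol, IntegerVector dims,
                               NumericVector voxel, NumericMatrix points,
                               double cutoff_sigmas = 3.0) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double dx = voxel[0], dy = voxel[1], dz = voxel[2];
  const R_xlen_t npts = points.nrow();
  double* v = REAL(vol);
  for (R_xlen_t p = 0; p < npts; ++p) {
    const double px = points(p, 0), py = points(p, 1), pz = points(p, 2);
    const double s = points(p, 3);
    const double rad = cutoff_sigmas * s;
    const double inv2s2 = 1.0 / (2.0 * s * s);
    int ix0 = (int)std::ceil((px - rad) / dx), ix1 = (int)std::floor((px + rad) / dx);
    int iy0 = (int)std::ceil((py - rad) / dy), iy1 = (int)std::floor((py + rad) / dy);
    int iz0 = (int)std::ceil((pz - rad) / dz), iz1 = (int)std::floor((pz + rad) / dz);
    if (ix0 < 0) ix0 = 0; if (ix1 > nx - 1) ix1 = nx - 1;
    if (iy0 < 0) iy0 = 0; if (iy1 > ny - 1) iy1 = ny - 1;
    if (iz0 < 0) iz0 = 0; if (iz1 > nz - 1) iz1 = nz - 1;
    for (int iz = iz0; iz <= iz1; ++iz) {
      const double ddz = iz * dz - pz;
      for (int iy = iy0; iy <= iy1; ++iy) {
        const double ddy = iy * dy - py;
        const double d2yz = ddy * ddy + ddz * ddz;
        const R_xlen_t base = (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz);
        for (int ix = ix0; ix <= ix1; ++ix) {
          const double ddx = ix * dx - px;
          const double d2 = ddx * ddx + d2yz;
          const double a = std::exp(-d2 * inv2s2);
          if (a > v[base + ix]) v[base + ix] = a;
        }
      }
    }
  }
  return vol;
}

// Separable 2D convolution with replicate (edge-clamp) padding.
// m is nx x ny; kx filters along dim 1, ky along dim 2. Kernels must have
// odd length.
// [[Rcpp::export]]
NumericMatrix cpp_sep_conv2(NumericMatrix m, NumericVector kx, NumericVector ky) {
  const int nx = m.nrow(), ny = m.ncol();
  const int hx = ((int)kx.size() - 1) / 2, hy = ((int)ky.size() - 1) / 2;
  NumericMatrix tmp(nx, ny), out(nx, ny);
  const double *pm = REAL(m);
  double *pt = REAL(tmp), *po = REAL(out);
  const double *wx = REAL(kx), *wy = REAL(ky);
  // dim 1 (contiguous within a column)
  for (int j = 0; j < ny; ++j) {
    const double *col = pm + (R_xlen_t)nx * j;
    double *dst = pt + (R_xlen_t)nx * j;
    const int lo = std::min(hx, nx), hi = std::max(0, nx - hx);
    for (int i = 0; i < lo; ++i) {
      double acc = 0.0;
      for (int t = -hx; t <= hx; ++t) {
        int ii = i + t;
        if (ii < 0) ii = 0; else if (ii > nx - 1) ii = nx - 1;
        acc += wx[t + hx] * col[ii];
      }
      dst[i] = acc;
    }
    for (int i = lo; i < hi; ++i) {
      double acc = 0.0;
      const double *src = col + i - hx;
      for (int t = 0; t <= 2 * hx; ++t) acc += wx[t] * src[t];
      dst[i] = acc;
    }
    for (int i = std::max(lo, hi); i < nx; ++i) {
      double acc = 0.0;
      for (int t = -hx; t <= hx; ++t) {
        int ii = i + t;
        if (ii < 0) ii = 0; else if (ii > nx - 1) ii = nx - 1;
        acc += wx[t + hx] * col[ii];
      }
      dst[i] = acc;
    }
  }
  // dim 2: accumulate whole shifted columns (stays cache-friendly)
  for (int j = 0; j < ny; ++j) {
    double *dst = po + (R_xlen_t)nx * j;
    for (int t = -hy; t <= hy; ++t) {
      int jj = j + t;
      if (jj < 0) jj = 0; else if (jj > ny - 1) jj = ny - 1;
      const double w = wy[t + hy];
      const double *src = pt + (R_xlen_t)nx * jj;
      for (int i = 0; i < nx; ++i) dst[i] += w * src[i];
    }
  }
  return out;
}

static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                 double step) {
  // Felzenszwalb & Huttenlocher lower-envelope 1D squared distance transform
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INFINITY; z[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double qq = q * step;
    double s;
    while (true) {
      double vv = v[k] * step;
      s = ((f[q] + qq * qq) - (f[v[k]] + vv * vv)) / (2 * qq - 2 * vv);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double qq = q * step;
    while (z[k + 1] < qq) ++k;
    double vv = v[k] * step;
    d[q] = (qq - vv) * (qq - vv) + f[v[k]];
  }
}

// Exact Euclidean distance (micrometres) from each TRUE pixel to the nearest
// FALSE pixel, with anisotropic pixel spacing. FALSE pixels get distance 0.
// With border_background, pixels outside the image count as background
// (distances are clamped at the border), the right convention for vessel
// radius estimation; without it the image edge is ignored (used for
// morphological dilation).
// [[Rcpp::export]]
NumericMatrix cpp_edt2(LogicalMatrix mask, double dx, double dy,
                       bool border_background = true) {
  const int nx = mask.nrow(), ny = mask.ncol();
  const double big = 1e30;
  NumericMatrix d2(nx, ny);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i)
      d2(i, j) = mask(i, j) ? big : 0.0;
  std::vector<double> f(std::max(nx, ny)), g(std::max(nx, ny));
  // pass along x
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) f[i] = d2(i, j);
    dt1d(f, g, nx, dx);
    for (int i = 0; i < nx; ++i) d2(i, j) = g[i];
  }
  // pass along y
  for (int i = 0; i < nx; ++i) {
    for (int j = 0; j < ny; ++j) f[j] = d2(i, j);
    dt1d(f, g, ny, dy);
    for (int j = 0; j < ny; ++j) d2(i, j) = g[j];
  }
  // clamp to the image border: treat outside as background
  NumericMatrix out(nx, ny);
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      double dd = std::sqrt(d2(i, j));
      if (border_background && mask(i, j)) {
        double db = std::min(std::min((i + 1) * dx, (nx - i) * dx),
                             std::min((j + 1) * dy, (ny - j) * dy));
        if (db < dd) dd = db;
      }
      out(i, j) = dd;
    }
  }
  return out;
}

// Connected-component labeling of a binary image (BFS), 4- or 8-connectivity.
// Returns integer labels, 0 = background, components numbered from 1.
// [[Rcpp::export]]
IntegerMatrix cpp_label(LogicalMatrix mask, int connectivity = 8) {
  const int nx = mask.nrow(), ny = mask.ncol();
  IntegerMatrix lab(nx, ny);
  std::fill(lab.begin(), lab.end(), 0);
  const int dx8[] = {1, -1, 0, 0, 1, 1, -1, -1};
  const int dy8[] = {0, 0, 1, -1, 1, -1, 1, -1};
  const int nn = (connectivity == 8) ? 8 : 4;
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      lab(i, j) = ++next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        std::pair<int, int> c = q.front(); q.pop();
        for (int t = 0; t < nn; ++t) {
          int ii = c.first + dx8[t], jj = c.second + dy8[t];
          if (ii < 0 || jj < 0 || ii >= nx || jj >= ny) continue;
          if (mask(ii, jj) && !lab(ii, jj)) {
            lab(ii, jj) = next;
            q.push(std::make_pair(ii, jj));
          }
        }
      }
    }
  }
  return lab;
}

// Zhang-Suen iterative thinning to a 1-pixel-wide, topology-preserving
// skeleton. Pixels outside the image count as background.
// [[Rcpp::export]]
LogicalMatrix cpp_thin(LogicalMatrix mask) {
  const int nx = mask.nrow(), ny = mask.ncol();
  LogicalMatrix im = clone(mask);
  std::vector<std::pair<int, int> > del;
  bool changed = true;
  auto at = [&](int i, int j) -> int {
    if (i < 0 || j < 0 || i >= nx || j >= ny) return 0;
    return im(i, j) ? 1 : 0;
  };
  while (changed) {
    changed = false;
    for (int sub = 0; sub < 2; ++sub) {
      del.clear();
      for (int j = 0; j < ny; ++j) {
        for (int i = 0; i < nx; ++i) {
          if (!im(i, j)) continue;
          // neighbors clockwise from north (N, NE, E, SE, S, SW, W, NW),
          // with +y as "south" (orientation does not matter for thinning)
          int p[8] = {at(i, j - 1), at(i + 1, j - 1), at(i + 1, j),
                      at(i + 1, j + 1), at(i, j + 1), at(i - 1, j + 1),
                      at(i - 1, j), at(i - 1, j - 1)};
          int B = 0, A = 0;
          for (int t = 0; t < 8; ++t) {
            B += p[t];
            if (p[t] == 0 && p[(t + 1) % 8] == 1) ++A;
          }
          if (B < 2 || B > 6 || A != 1) continue;
          if (sub == 0) {
            if (p[0] * p[2] * p[4] != 0) continue;
            if (p[2] * p[4] * p[6] != 0) continue;
          } else {
            if (p[0] * p[2] * p[6] != 0) continue;
            if (p[0] * p[4] * p[6] != 0) continue;
          }
          del.push_back(std::make_pair(i, j));
        }
      }
      if (!del.empty()) changed = true;
      for (size_t t = 0; t < del.size(); ++t)
        im(del[t].first, del[t].second) = FALSE;
    }
  }
  return im;
}
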