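// Voxel-grid primitives: connected components, flood fill, dilation,
// capsule rasterization, rigid resampling. All grids are passed as flat
// vectors in R's column-major order with dims (nx, ny, nz); voxel i (0-based)
// has its center at coordinate i + 0.5 in voxel units.
#include <RcppArmadillo.h>
#include <queue>
#include <cmath>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline long flat(int i, int j, int k, int nx, int ny) {
  return (long)i + (long)nx * ((long)j + (long)ny * (long)k);
}

// 26-connected component labelling of a logical mask.
// Returns labels (0 = background) and component sizes.
// [[Rcpp::export]]
List cpp_label26(const LogicalVector &mask, const IntegerVector &dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long n = (long)nx * ny * nz;
  IntegerVector labels(n, 0);
  std::vector<int> sizes;
  int cur = 0;
  std::vector<long> stack;
  for (long s = 0; s < n; ++s) {
    if (!mask[s] || labels[s] != 0) continue;
    ++cur;
    int size = 0;
    stack.push_back(s);
    labels[s] = cur;
    while (!stack.empty()) {
      long v = stack.back(); stack.pop_back();
      ++size;
      int i = v % nx, j = (v / nx) % ny, k = v / ((long)nx * ny);
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
            long w = flat(ii, jj, kk, nx, ny);
            if (mask[w] && labels[w] == 0) { labels[w] = cur; stack.push_back(w); }
          }
    }
    sizes.push_back(size);
  }
  return List::create(_["labels"] = labels, _["sizes"] = wrap(sizes));
}

// 6-connected flood fill from a seed over voxels NOT in `blocked`.
// [[Rcpp::export]]
LogicalVector cpp_flood6(const LogicalVector &blocked, const IntegerVector &dims,
                         const long seed) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long n = (long)nx * ny * nz;
  LogicalVector vis(n, false);
  if (seed < 0 || seed >= n || blocked[seed]) return vis;
  std::vector<long> stack;
  stack.push_back(seed);
  vis[seed] = true;
  const int di[6] = {1, -1, 0, 0, 0, 0};
  const int dj[6] = {0, 0, 1, -1, 0, 0};
  const int dk[6] = {0, 0, 0, 0, 1, -1};
  while (!stack.empty()) {
    long v = stack.back(); stack.pop_back();
    int i = v % nx, j = (v / nx) % ny, k = v / ((long)nx * ny);
    for (int q = 0; q < 6; ++q) {
      int ii = i + di[q], jj = j + dj[q], kk = k + dk[q];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
      long w = flat(ii, jj, kk, nx, ny);
      if (!blocked[w] && !vis[w]) { vis[w] = true; stack.push_back(w); }
    }
  }
  return vis;
}

// One-voxel 26-neighbourhood dilation.
// [[Rcpp::export]]
LogicalVector cpp_dilate26(const LogicalVector &mask, const IntegerVector &dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long n = (long)nx * ny * nz;
  LogicalVector out(n, false);
  for (long s = 0; s < n; ++s) {
    if (!mask[s]) continue;
    int i = s % nx, j = (s / nx) % ny, k = s / ((long)nx * ny);
    for (int dk = -1; dk <= 1; ++dk)
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          int ii = i + di, jj = j + dj, kk = k + dk;
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
          out[flat(ii, jj, kk, nx, ny)] = true;
        }
  }
  return out;
}

// Rasterize a union of capsules (line segments with radius, voxel units)
// into a logical mask. seg columns: x1 y1 z1 x2 y2 z2 r.
// [[Rcpp::export]]
LogicalVector cpp_raster_capsules(const NumericMatrix &seg, const IntegerVector &dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long n = (long)nx * ny * nz;
  LogicalVector out(n, false);
  for (int s = 0; s < seg.nrow(); ++s) {
    double ax = seg(s, 0), ay = seg(s, 1), az = seg(s, 2);
    double bx = seg(s, 3), by = seg(s, 4), bz = seg(s, 5), r = seg(s, 6);
    double r2 = r * r;
    double ux = bx - ax, uy = by - ay, uz = bz - az;
    double L2 = ux * ux + uy * uy + uz * uz;
    int i0 = std::max(0, (int)std::floor(std::min(ax, bx) - r - 1.0));
    int i1 = std::min(nx - 1, (int)std::ceil(std::max(ax, bx) + r));
    int j0 = std::max(0, (int)std::floor(std::min(ay, by) - r - 1.0));
    int j1 = std::min(ny - 1, (int)std::ceil(std::max(ay, by) + r));
    int k0 = std::max(0, (int)std::floor(std::min(az, bz) - r - 1.0));
    int k1 = std::min(nz - 1, (int)std::ceil(std::max(az, bz) + r));
    for (int k = k0; k <= k1; ++k)
      for (int j = j0; j <= j1; ++j)
        for (int i = i0; i <= i1; ++i) {
          double px = i + 0.5 - ax, py = j + 0.5 - ay, pz = k + 0.5 - az;
          double t = (L2 > 0) ? (px * ux + py * uy + pz * uz) / L2 : 0.0;
          if (t < 0) t = 0; else if (t > 1) t = 1;
          double dx = px - t * ux, dy = py - t * uy, dz = pz - t * uz;
          if (dx * dx + dy * dy + dz * dz <= r2)
            out[flat(i, j, k, nx, ny)] = true;
        }
  }
  return out;
}

static inline double trilin(const NumericVector &v, int nx, int ny, int nz,
                            double x, double y, double z) {
  // x,y,z in voxel units (center of voxel i at i+0.5); 0 outside.
  double u = x - 0.5, w = y - 0.5, q = z - 0.5;
  int i0 = (int)std::floor(u), j0 = (int)std::floor(w), k0 = (int)std::floor(q);
  double fx = u - i0, fy = w - j0, fz = q - k0;
  double acc = 0.0;
  for (int dk = 0; dk <= 1; ++dk)
    for (int dj = 0; dj <= 1; ++dj)
      for (int di = 0; di <= 1; ++di) {
        int i = i0 + di, j = j0 + dj, k = k0 + dk;
        if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) continue;
        double wgt = (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) * (dk ? fz : 1 - fz);
        acc += wgt * v[flat(i, j, k, nx, ny)];
      }
  return acc;
}

// Resample a source grid under the rigid map y = R x + t (voxel units,
// source -> destination): for every destination voxel center y the source is
// sampled at x = R^T (y - t). trilinear = false uses nearest-voxel lookup.
// [[Rcpp::export]]
NumericVector cpp_resample_rigid(const NumericVector &src, const IntegerVector &sdims,
                                 const NumericMatrix &R, const NumericVector &t,
                                 const IntegerVector &ddims, const bool trilinear) {
  const int sx = sdims[0], sy = sdims[1], sz = sdims[2];
  const int dx = ddims[0], dy = ddims[1], dz = ddims[2];
  NumericVector out((long)dx * dy * dz);
  double Rt[3][3];
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b) Rt[a][b] = R(b, a);
  long s = 0;
  for (int k = 0; k < dz; ++k)
    for (int j = 0; j < dy; ++j)
      for (int i = 0; i < dx; ++i, ++s) {
        double yx = i + 0.5 - t[0], yy = j + 0.5 - t[1], yz = k + 0.5 - t[2];
        double x0 = Rt[0][0] * yx + Rt[0][1] * yy + Rt[0][2] * yz;
        double x1 = Rt[1][0] * yx + Rt[1][1] * yy + Rt[1][2] * yz;
        double x2 = Rt[2][0] * yx + Rt[2][1] * yy + Rt[2][2] * yz;
        if (trilinear) {
          out[s] = trilin(src, sx, sy, sz, x0, x1, x2);
        } else {
          int ii = (int)std::floor(x0), jj = (int)std::floor(x1), kk = (int)std::floor(x2);
          out[s] = (ii < 0 || jj < 0 || kk < 0 || ii >= sx || jj >= sy || kk >= sz)
                     ? 0.0 : src[flat(ii, jj, kk, sx, sy)];
        }
      }
  return out;
}

// Trilinear samples of a grid at arbitrary points (voxel units).
// [[Rcpp::export]]
NumericVector cpp_sample_trilinear(const NumericVector &src, const IntegerVector &sdims,
                                   const NumericMatrix &pts) {
  const int sx = sdims[0], sy = sdims[1], sz = sdims[2];
  NumericVector out(pts.nrow());
  for (int p = 0; p < pts.nrow(); ++p)
    out[p] = trilin(src, sx, sy, sz, pts(p, 0), pts(p, 1), pts(p, 2));
  return out;
}

// For each point of A, squared distance to the nearest point of B.
// [[Rcpp::export]]
NumericVector cpp_nn_dist2(const NumericMatrix &A, const NumericMatrix &B) {
  NumericVector out(A.nrow());
  for (int i = 0; i < A.nrow(); ++i) {
    double best = R_PosInf;
    double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
    for (int j = 0; j < B.nrow(); ++j) {
      double dx = ax - B(j, 0), dy = ay - B(j, 1), dz = az - B(j, 2);
      double d = dx * dx + dy * dy + dz * dz;
      if (d < best) best = d;
    }
    out[i] = best;
  }
  return out;
}
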