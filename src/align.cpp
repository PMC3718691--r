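// Rigid registration kernels: exhaustive density-overlap search over an
// Euler-angle/translation grid, and point-to-point ICP with Kabsch updates.
#include <RcppArmadillo.h>
#include <cmath>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat33 euler_deg(double ax, double ay, double az) {
  const double d = M_PI / 180.0;
  double cx = std::cos(ax * d), sx = std::sin(ax * d);
  double cy = std::cos(ay * d), sy = std::sin(ay * d);
  double cz = std::cos(az * d), sz = std::sin(az * d);
  arma::mat33 Rx = {{1, 0, 0}, {0, cx, -sx}, {0, sx, cx}};
  arma::mat33 Ry = {{cy, 0, sy}, {0, 1, 0}, {-sy, 0, cy}};
  arma::mat33 Rz = {{cz, -sz, 0}, {sz, cz, 0}, {0, 0, 1}};
  return Rz * Ry * Rx;
}

// Exhaustive search over delta rotations (one angle grid per Euler axis,
// composed after Rinit) and integer translations. Points are moving-frame
// coordinates relative to the rotation center, in voxel units of the fixed
// grid; `shift` is where the moving center lands in the fixed grid. Score is
// sum over points of w * fixed(nearest voxel). Ties break toward the smaller
// delta rotation, then the smaller translation.
// [[Rcpp::export]]
List cpp_density_search(const NumericMatrix &P, const NumericVector &w,
                        const NumericVector &fixedvol, const IntegerVector &fdims,
                        const NumericMatrix &Rinit, const NumericVector &shift,
                        const NumericVector &ax_grid, const NumericVector &ay_grid,
                        const NumericVector &az_grid, const int tmax) {
  const int nx = fdims[0], ny = fdims[1], nz = fdims[2];
  const int n = P.nrow();
  arma::mat33 Ri;
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b) Ri(a, b) = Rinit(a, b);
  arma::mat Pm(3, n);
  for (int i = 0; i < n; ++i) {
    Pm(0, i) = P(i, 0); Pm(1, i) = P(i, 1); Pm(2, i) = P(i, 2);
  }
  const int nt = 2 * tmax + 1;
  std::vector<double> tscore(nt * nt * nt);
  std::vector<int> ix(n), iy(n), iz(n);

  double best = -std::numeric_limits<double>::infinity();
  double best_rotmag = 0, best_tmag = 0;
  double bax = 0, bay = 0, baz = 0;
  int btx = 0, bty = 0, btz = 0;

  for (int ia = 0; ia < ax_grid.size(); ++ia)
    for (int ib = 0; ib < ay_grid.size(); ++ib)
      for (int ic = 0; ic < az_grid.size(); ++ic) {
        double ax = ax_grid[ia], ay = ay_grid[ib], az = az_grid[ic];
        arma::mat33 R = Ri * euler_deg(ax, ay, az);
        double rotmag = ax * ax + ay * ay + az * az;
        for (int i = 0; i < n; ++i) {
          double qx = R(0,0)*Pm(0,i) + R(0,1)*Pm(1,i) + R(0,2)*Pm(2,i) + shift[0];
          double qy = R(1,0)*Pm(0,i) + R(1,1)*Pm(1,i) + R(1,2)*Pm(2,i) + shift[1];
          double qz = R(2,0)*Pm(0,i) + R(2,1)*Pm(1,i) + R(2,2)*Pm(2,i) + shift[2];
          ix[i] = (int)std::floor(qx); iy[i] = (int)std::floor(qy); iz[i] = (int)std::floor(qz);
        }
        std::fill(tscore.begin(), tscore.end(), 0.0);
        for (int i = 0; i < n; ++i) {
          const double wi = w[i];
          int s = 0;
          for (int tz = -tmax; tz <= tmax; ++tz) {
            int kk = iz[i] + tz;
            if (kk < 0 || kk >= nz) { s += nt * nt; continue; }
            for (int ty = -tmax; ty <= tmax; ++ty) {
              int jj = iy[i] + ty;
              if (jj < 0 || jj >= ny) { s += nt; continue; }
              long base = (long)nx * ((long)jj + (long)ny * kk);
              for (int tx = -tmax; tx <= tmax; ++tx, ++s) {
                int ii = ix[i] + tx;
                if (ii < 0 || ii >= nx) continue;
                tscore[s] += wi * fixedvol[base + ii];
              }
            }
          }
        }
        int s = 0;
        for (int tz = -tmax; tz <= tmax; ++tz)
          for (int ty = -tmax; ty <= tmax; ++ty)
            for (int tx = -tmax; tx <= tmax; ++tx, ++s) {
              double sc = tscore[s];
              double tmag = (double)tx * tx + ty * ty + tz * tz;
              bool take = sc > best;
              if (!take && sc == best)
                take = rotmag < best_rotmag ||
                       (rotmag == best_rotmag && tmag < best_tmag);
              if (take) {
                best = sc; best_rotmag = rotmag; best_tmag = tmag;
                bax = ax; bay = ay; baz = az; btx = tx; bty = ty; btz = tz;
              }
            }
      }
  return List::create(_["score"] = best,
                      _["angles"] = NumericVector::create(bax, bay, baz),
                      _["dt"] = NumericVector::create(btx, bty, btz));
}

// Score of a fixed rigid placement (nearest-voxel lookup), same conventions.
// [[Rcpp::export]]
double cpp_density_score(const NumericMatrix &P, const NumericVector &w,
                         const NumericVector &fixedvol, const IntegerVector &fdims,
                         const NumericMatrix &R, const NumericVector &shift) {
  const int nx = fdims[0], ny = fdims[1], nz = fdims[2];
  double acc = 0;
  for (int i = 0; i < P.nrow(); ++i) {
    double qx = R(0,0)*P(i,0) + R(0,1)*P(i,1) + R(0,2)*P(i,2) + shift[0];
    double qy = R(1,0)*P(i,0) + R(1,1)*P(i,1) + R(1,2)*P(i,2) + shift[1];
    double qz = R(2,0)*P(i,0) + R(2,1)*P(i,1) + R(2,2)*P(i,2) + shift[2];
    int ii = (int)std::floor(qx), jj = (int)std::floor(qy), kk = (int)std::floor(qz);
    if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
    acc += w[i] * fixedvol[(long)ii + (long)nx * ((long)jj + (long)ny * kk)];
  }
  return acc;
}

// Point-to-point ICP: closest-vertex correspondences (brute force) and
// least-squares rigid (Kabsch) updates, iterated until the relative change
// in mean closest-point distance falls below tol. `trim` keeps only that
// fraction of best-matched points in each update (robustness to
// non-overlapping structure); the reported distance is untrimmed.
// [[Rcpp::export]]
List cpp_icp(const NumericMatrix &A, const NumericMatrix &B,
             const NumericMatrix &R0, const NumericVector &t0,
             const int max_iter, const double tol, const double trim = 1.0) {
  const int nA = A.nrow(), nB = B.nrow();
  arma::mat Am(3, nA), Bm(3, nB);
  for (int i = 0; i < nA; ++i) { Am(0,i)=A(i,0); Am(1,i)=A(i,1); Am(2,i)=A(i,2); }
  for (int j = 0; j < nB; ++j) { Bm(0,j)=B(j,0); Bm(1,j)=B(j,1); Bm(2,j)=B(j,2); }
  arma::mat33 R;
  arma::vec3 t;
  for (int a = 0; a < 3; ++a) {
    t(a) = t0[a];
    for (int b = 0; b < 3; ++b) R(a, b) = R0(a, b);
  }
  double prev = std::numeric_limits<double>::infinity(), meand = prev;
  int it = 0;
  bool converged = false;
  std::vector<int> corr(nA);
  std::vector<double> dists(nA);
  const int nkeep = std::max(3, (int)std::floor(trim * nA));
  for (it = 0; it < max_iter; ++it) {
    arma::mat TA = R * Am;
    TA.each_col() += t;
    double acc = 0;
    for (int i = 0; i < nA; ++i) {
      double bx = TA(0,i), by = TA(1,i), bz = TA(2,i), bestd = R_PosInf;
      int bj = 0;
      for (int j = 0; j < nB; ++j) {
        double dx = bx - Bm(0,j), dy = by - Bm(1,j), dz = bz - Bm(2,j);
        double d = dx*dx + dy*dy + dz*dz;
        if (d < bestd) { bestd = d; bj = j; }
      }
      corr[i] = bj;
      dists[i] = std::sqrt(bestd);
      acc += dists[i];
    }
    meand = acc / nA;
    if (std::isfinite(prev) &&
        std::fabs(prev - meand) <= tol * std::max(prev, 1e-12)) {
      converged = true;
      break;
    }
    prev = meand;
    // keep the best-matched fraction for the rigid update
    std::vector<int> keep(nA);
    for (int i = 0; i < nA; ++i) keep[i] = i;
    if (nkeep < nA) {
      std::nth_element(keep.begin(), keep.begin() + nkeep, keep.end(),
                       [&](int a, int b) { return dists[a] < dists[b]; });
      keep.resize(nkeep);
    }
    const int nk = (int)keep.size();
    // Kabsch update mapping kept A points onto their matched B points
    arma::mat Ak(3, nk), Bc(3, nk);
    for (int i = 0; i < nk; ++i) {
      Ak.col(i) = Am.col(keep[i]);
      Bc.col(i) = Bm.col(corr[keep[i]]);
    }
    arma::vec3 ca = arma::mean(Ak, 1);
    arma::vec3 cb = arma::mean(Bc, 1);
    arma::mat H = (Ak.each_col() - ca) * (Bc.each_col() - cb).t();
    arma::mat U, V;
    arma::vec s;
    if (!arma::svd(U, s, V, H)) break;
    arma::mat33 Rn = V * U.t();
    if (arma::det(Rn) < 0) { V.col(2) *= -1.0; Rn = V * U.t(); }
    R = Rn;
    t = cb - R * ca;
  }
  return List::create(_["R"] = wrap(arma::mat(R)), _["t"] = wrap(arma::vec(t)),
                      _["dist"] = meand, _["iterations"] = it,
                      _["converged"] = converged);
}
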