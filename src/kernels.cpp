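#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sample a gridded image (scalar or multi-component, column-major
// [nx, ny, nz, ncomp]) at continuous 0-based voxel coordinates.
// mode 0 = trilinear, 1 = nearest. Out-of-hull samples are NaN; the caller
// applies its policy (error / zero / drop). The trilinear hull is the node
// hull [0, n-1]; the nearest hull extends half a voxel beyond it.
// [[Rcpp::export]]
NumericMatrix cppSampleGrid(NumericVector arr, IntegerVector dims, int ncomp,
                            NumericMatrix vox, int mode) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = vox.nrow();
  const R_xlen_t planesz = (R_xlen_t)nx * ny * nz;
  NumericMatrix out(n, ncomp);
  const double nan = R_NaN;

  for (R_xlen_t i = 0; i < n; ++i) {
    const double x = vox(i, 0), y = vox(i, 1), z = vox(i, 2);
    if (!R_finite(x) || !R_finite(y) || !R_finite(z)) {
      for (int c = 0; c < ncomp; ++c) out(i, c) = nan;
      continue;
    }
    if (mode == 1) {
      const long ix = lround(x), iy = lround(y), iz = lround(z);
      if (ix < 0 || ix >= nx || iy < 0 || iy >= ny || iz < 0 || iz >= nz) {
        for (int c = 0; c < ncomp; ++c) out(i, c) = nan;
      } else {
        const R_xlen_t base = ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz);
        for (int c = 0; c < ncomp; ++c) out(i, c) = arr[base + c * planesz];
      }
      continue;
    }
    if (x < 0 || x > nx - 1 || y < 0 || y > ny - 1 || z < 0 || z > nz - 1) {
      for (int c = 0; c < ncomp; ++c) out(i, c) = nan;
      continue;
    }
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
    if (x0 > nx - 2) x0 = nx - 2;
    if (y0 > ny - 2) y0 = ny - 2;
    if (z0 > nz - 2) z0 = nz - 2;
    if (nx == 1) x0 = 0;
    if (ny == 1) y0 = 0;
    if (nz == 1) z0 = 0;
    const double fx = x - x0, fy = y - y0, fz = z - z0;
    const double wx[2] = {1 - fx, fx}, wy[2] = {1 - fy, fy}, wz[2] = {1 - fz, fz};
    for (int c = 0; c < ncomp; ++c) {
      double acc = 0.0;
      for (int dz = 0; dz < 2; ++dz) {
        if (wz[dz] == 0 && nz > 1) continue;
        const int zz = (nz == 1) ? 0 : z0 + dz;
        for (int dy = 0; dy < 2; ++dy) {
          if (wy[dy] == 0 && ny > 1) continue;
          const int yy = (ny == 1) ? 0 : y0 + dy;
          for (int dx = 0; dx < 2; ++dx) {
            if (wx[dx] == 0 && nx > 1) continue;
            const int xx = (nx == 1) ? 0 : x0 + dx;
            const double w = wx[dx] * wy[dy] * wz[dz];
            if (w == 0) continue;
            acc += w * arr[xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)
                           + c * planesz];
          }
        }
      }
      out(i, c) = acc;
    }
  }
  return out;
}

// Index (1-based) of the Euclidean-nearest reference point for every query
// point; ties resolve to the lowest reference index (strict improvement
// required to switch).
// [[Rcpp::export]]
IntegerVector cppNearestPoint(NumericMatrix ref, NumericMatrix query) {
  const R_xlen_t nr = ref.nrow(), nq = query.nrow();
  IntegerVector out(nq);
  std::vector<double> rx(nr), ry(nr), rz(nr);
  for (R_xlen_t j = 0; j < nr; ++j) {
    rx[j] = ref(j, 0); ry[j] = ref(j, 1); rz[j] = ref(j, 2);
  }
  for (R_xlen_t i = 0; i < nq; ++i) {
    const double qx = query(i, 0), qy = query(i, 1), qz = query(i, 2);
    double best = R_PosInf;
    R_xlen_t bj = 0;
    for (R_xlen_t j = 0; j < nr; ++j) {
      const double dx = qx - rx[j], dy = qy - ry[j], dz = qz - rz[j];
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) { best = d2; bj = j; }
    }
    out[i] = (int)(bj + 1);
  }
  return out;
}
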