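#include <Rcpp.h>
#include <cmath>
#include <limits>
#include <vector>

using namespace Rcpp;

// 1-D squared distance transform (Felzenszwalb & Huttenlocher), lower envelope
// of parabolas. f holds squared distances on input, overwritten on output.
static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z, int n) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) {
        --k;
      } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
  for (int q = 0; q < n; ++q) f[q] = d[q];
}

// Exact squared Euclidean distance transform of a binary volume: for each
// foreground (bone) voxel, squared center-to-center distance to the nearest
// background voxel inside the volume. The volume boundary is not treated as
// background, so structures touching the faces are not eroded by the border.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector vol, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  // large finite sentinel: infinities break the parabola intersections
  const double BIG = 1e15;
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = vol[i] ? BIG : 0.0;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
      for (int i = 0; i < nx; ++i) f[i] = out[base + i];
      dt1d(f, d, v, z, nx);
      for (int i = 0; i < nx; ++i) out[base + i] = f[i];
    }
  // pass along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + i;
      for (int j = 0; j < ny; ++j) f[j] = out[base + (R_xlen_t)j * nx];
      dt1d(f, d, v, z, ny);
      for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)j * nx] = f[j];
    }
  // pass along z
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)j * nx + i;
      for (int k = 0; k < nz; ++k) f[k] = out[base + (R_xlen_t)k * nx * ny];
      dt1d(f, d, v, z, nz);
      for (int k = 0; k < nz; ++k) out[base + (R_xlen_t)k * nx * ny] = f[k];
    }
  // no background reachable -> undefined distance
  for (R_xlen_t i = 0; i < n; ++i)
    if (out[i] >= 1e14) out[i] = R_PosInf;
  return out;
}

// Local thickness map (sphere fitting): thickness at a bone voxel p is the
// diameter 2*r(x) of the largest inscribed sphere that contains p, where
// r(x) = sqrt(edt_sq(x)) is the inscribed-sphere radius centred at x. Every
// bone voxel is a candidate centre; a centre is skipped when a direct
// neighbour's sphere provably contains its own (a cheap ridge filter that
// does not change the result). Background voxels get 0.
// [[Rcpp::export]]
NumericVector cpp_local_thickness(NumericVector edt_sq, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector thick(n);

  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t idx = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx + i;
        double r2 = edt_sq[idx];
        if (!(r2 > 0.0) || !R_finite(r2)) continue;
        double r = std::sqrt(r2);
        // dominance test against the 6 face neighbours
        bool dominated = false;
        const int off[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
        for (int m = 0; m < 6 && !dominated; ++m) {
          int ii = i + off[m][0], jj = j + off[m][1], kk = k + off[m][2];
          if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
            continue;
          R_xlen_t nidx = (R_xlen_t)kk * nx * ny + (R_xlen_t)jj * nx + ii;
          double rn2 = edt_sq[nidx];
          if (R_finite(rn2) && rn2 > 0.0 && std::sqrt(rn2) >= r + 1.0)
            dominated = true;
        }
        if (dominated) continue;
        int ir = (int)std::floor(r);
        double dia = 2.0 * r;
        int k0 = std::max(0, k - ir), k1 = std::min(nz - 1, k + ir);
        for (int kk = k0; kk <= k1; ++kk) {
          double dz = kk - (double)k;
          double rem2z = r2 - dz * dz;
          if (rem2z <= 0.0) continue;
          int jr = (int)std::floor(std::sqrt(rem2z));
          int j0 = std::max(0, j - jr), j1 = std::min(ny - 1, j + jr);
          for (int jj = j0; jj <= j1; ++jj) {
            double dy = jj - (double)j;
            double rem2 = rem2z - dy * dy;
            if (rem2 <= 0.0) continue;
            int irx = (int)std::floor(std::sqrt(rem2));
            int i0 = std::max(0, i - irx), i1 = std::min(nx - 1, i + irx);
            R_xlen_t rowbase = (R_xlen_t)kk * nx * ny + (R_xlen_t)jj * nx;
            for (int ii = i0; ii <= i1; ++ii) {
              double dx = ii - (double)i;
              if (dx * dx < rem2 && thick[rowbase + ii] < dia)
                thick[rowbase + ii] = dia;
            }
          }
        }
      }
  return thick;
}
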