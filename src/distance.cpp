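#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// 1-D squared-distance transform (lower envelope of parabolas) on n samples
// at positions i*w, i = 0..n-1.  f holds squared distances on entry (INF
// where no source has been seen); result written to out.
static void dt1d(const std::vector<double>& f, int n, double w,
                 std::vector<int>& v, std::vector<double>& z,
                 std::vector<double>& out) {
  int q0 = 0;
  while (q0 < n && f[q0] == INF) ++q0;
  if (q0 == n) {
    for (int q = 0; q < n; ++q) out[q] = INF;
    return;
  }
  const double w2 = w * w;
  int k = 0;
  v[0] = q0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = q0 + 1; q < n; ++q) {
    if (f[q] == INF) continue;
    double s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
               (2.0 * w2 * (q - v[k]));
    while (s <= z[k]) {
      --k;
      s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
          (2.0 * w2 * (q - v[k]));
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    const double d = w * (q - v[k]);
    out[q] = d * d + f[v[k]];
  }
}

// Squared Euclidean distance (mm^2) from every voxel center to the nearest
// TRUE voxel center, honouring anisotropic spacing.  INF where the grid has
// no TRUE voxel (callers guard against empty masks).
// [[Rcpp::export(name = ".edt_sq")]]
NumericVector edt_sq(LogicalVector mask, IntegerVector dims, NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector d(n);
  for (R_xlen_t i = 0; i < n; ++i) d[i] = mask[i] ? 0.0 : INF;

  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), out(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x (fastest-varying index)
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      const R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
      for (int i = 0; i < nx; ++i) f[i] = d[base + i];
      dt1d(f, nx, spacing[0], v, z, out);
      for (int i = 0; i < nx; ++i) d[base + i] = out[i];
    }

  // pass along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      const R_xlen_t base = (R_xlen_t)k * nx * ny + i;
      for (int j = 0; j < ny; ++j) f[j] = d[base + (R_xlen_t)j * nx];
      dt1d(f, ny, spacing[1], v, z, out);
      for (int j = 0; j < ny; ++j) d[base + (R_xlen_t)j * nx] = out[j];
    }

  // pass along z
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      const R_xlen_t base = (R_xlen_t)j * nx + i;
      for (int k = 0; k < nz; ++k) f[k] = d[base + (R_xlen_t)k * nxy];
      dt1d(f, nz, spacing[2], v, z, out);
      for (int k = 0; k < nz; ++k) d[base + (R_xlen_t)k * nxy] = out[k];
    }

  return d;
}

// Even-odd (ray casting) point-in-polygon test for a batch of points.
// Half-open crossing rule keeps voxels on shared edges deterministic.
// [[Rcpp::export(name = ".points_in_polygon")]]
LogicalVector points_in_polygon(NumericVector px, NumericVector py,
                                NumericVector vx, NumericVector vy) {
  const R_xlen_t np = px.size();
  const int nv = vx.size();
  LogicalVector inside(np);
  for (R_xlen_t p = 0; p < np; ++p) {
    const double x = px[p], y = py[p];
    bool in = false;
    for (int i = 0, j = nv - 1; i < nv; j = i++) {
      const bool cross = ((vy[i] > y) != (vy[j] > y)) &&
        (x < (vx[j] - vx[i]) * (y - vy[i]) / (vy[j] - vy[i]) + vx[i]);
      if (cross) in = !in;
    }
    inside[p] = in;
  }
  return inside;
}
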