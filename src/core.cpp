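#include <Rcpp.h>
#include <vector>
#include <queue>
#include <array>
#include <cmath>
#include <limits>

using namespace Rcpp;

// ---- exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher) ----
//
// One-dimensional lower-envelope pass; applied separably along x, y, z.
// Input f holds 0 at "site" voxels and +inf elsewhere; output is the exact
// squared Euclidean distance (in voxel units) to the nearest site.

static void edt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                  std::vector<int>& v, std::vector<double>& z) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue; // empty parabola never contributes
    double s = 0.0;
    while (k >= 0) {
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k])
        --k;
      else
        break;
    }
    ++k;
    v[k] = q;
    z[k] = (k == 0) ? -INF : s;
    z[k + 1] = INF;
  }
  if (k < 0) { // no sites in this line
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  int kk = 0;
  for (int q = 0; q < n; ++q) {
    while (z[kk + 1] < q) ++kk;
    d[q] = (double)(q - v[kk]) * (q - v[kk]) + f[v[kk]];
  }
}

// [[Rcpp::export]]
NumericVector edt_sq_cpp(LogicalVector site, IntegerVector dims) {
  const double INF = std::numeric_limits<double>::infinity();
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = site[i] ? 0.0 : INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x (fastest-varying index)
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
      for (int i = 0; i < nx; ++i) f[i] = out[base + i];
      edt1d(f, d, nx, v, z);
      for (int i = 0; i < nx; ++i) out[base + i] = d[i];
    }
  // pass along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + i;
      for (int j = 0; j < ny; ++j) f[j] = out[base + (R_xlen_t)j * nx];
      edt1d(f, d, ny, v, z);
      for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)j * nx] = d[j];
    }
  // pass along z
  R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)j * nx + i;
      for (int k = 0; k < nz; ++k) f[k] = out[base + (R_xlen_t)k * nxy];
      edt1d(f, d, nz, v, z);
      for (int k = 0; k < nz; ++k) out[base + (R_xlen_t)k * nxy] = d[k];
    }
  return out;
}

// ---- trilinear interpolation at arbitrary (0-based) voxel coordinates ----
//
// Coordinates outside [0, dim-1] on any axis return `outside`.

// [[Rcpp::export]]
NumericVector trilinear_cpp(NumericVector arr, IntegerVector dims,
                            NumericMatrix coords, double outside) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t npts = coords.nrow();
  R_xlen_t nxy = (R_xlen_t)nx * ny;
  NumericVector out(npts);
  for (R_xlen_t p = 0; p < npts; ++p) {
    double x = coords(p, 0), y = coords(p, 1), z = coords(p, 2);
    if (!R_finite(x) || !R_finite(y) || !R_finite(z) ||
        x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1) {
      out[p] = outside;
      continue;
    }
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
    if (x0 == nx - 1) x0--;
    if (y0 == ny - 1) y0--;
    if (z0 == nz - 1) z0--;
    if (nx == 1) x0 = 0;
    if (ny == 1) y0 = 0;
    if (nz == 1) z0 = 0;
    double fx = x - x0, fy = y - y0, fz = z - z0;
    int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1),
        z1 = std::min(z0 + 1, nz - 1);
    double c000 = arr[x0 + (R_xlen_t)y0 * nx + (R_xlen_t)z0 * nxy];
    double c100 = arr[x1 + (R_xlen_t)y0 * nx + (R_xlen_t)z0 * nxy];
    double c010 = arr[x0 + (R_xlen_t)y1 * nx + (R_xlen_t)z0 * nxy];
    double c110 = arr[x1 + (R_xlen_t)y1 * nx + (R_xlen_t)z0 * nxy];
    double c001 = arr[x0 + (R_xlen_t)y0 * nx + (R_xlen_t)z1 * nxy];
    double c101 = arr[x1 + (R_xlen_t)y0 * nx + (R_xlen_t)z1 * nxy];
    double c011 = arr[x0 + (R_xlen_t)y1 * nx + (R_xlen_t)z1 * nxy];
    double c111 = arr[x1 + (R_xlen_t)y1 * nx + (R_xlen_t)z1 * nxy];
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

// ---- connected-component labelling (6- or 26-connectivity) ----

// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  R_xlen_t nxy = (R_xlen_t)nx * ny;
  IntegerVector lab(n, 0);
  std::vector<std::array<int, 3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manhattan = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manhattan != 1) continue;
        offs.push_back({dx, dy, dz});
      }
  int cur = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++cur;
    lab[s] = cur;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t p = q.front();
      q.pop();
      int z = (int)(p / nxy);
      int rem = (int)(p - (R_xlen_t)z * nxy);
      int y = rem / nx, x = rem % nx;
      for (auto& o : offs) {
        int xx = x + o[0], yy = y + o[1], zz = z + o[2];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
          continue;
        R_xlen_t pp = xx + (R_xlen_t)yy * nx + (R_xlen_t)zz * nxy;
        if (mask[pp] && lab[pp] == 0) {
          lab[pp] = cur;
          q.push(pp);
        }
      }
    }
  }
  return lab;
}
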