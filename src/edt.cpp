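#include <Rcpp.h>
#include <vector>
#include <algorithm>

// Separable squared Euclidean distance transform
// (Felzenszwalb & Huttenlocher lower-envelope-of-parabolas, exact).
// Seeds: 0 at background voxels, BIG at foreground; after the three axis
// passes each voxel holds its squared distance (voxel units) to the
// nearest background voxel. BIG is a finite sentinel well above any
// attainable squared distance, so the parabola intersections stay finite.

static const double BIG = 1e18;

static void dt1d(std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n) {
  int k = 0;
  v[0] = 0;
  z[0] = -BIG;
  z[1] = BIG;
  for (int q = 1; q < n; q++) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      k--;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = BIG;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    d[q] = (double)(q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// [[Rcpp::export]]
Rcpp::NumericVector edt_squared_cpp(Rcpp::LogicalVector grid,
                                    Rcpp::IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  Rcpp::NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = (grid[i] == TRUE) ? BIG : 0.0;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // x-axis (fastest varying)
  for (int iz = 0; iz < nz; iz++)
    for (int iy = 0; iy < ny; iy++) {
      R_xlen_t base = (R_xlen_t)iz * nx * ny + (R_xlen_t)iy * nx;
      for (int ix = 0; ix < nx; ix++) f[ix] = out[base + ix];
      dt1d(f, d, v, z, nx);
      for (int ix = 0; ix < nx; ix++) out[base + ix] = d[ix];
    }
  // y-axis
  for (int iz = 0; iz < nz; iz++)
    for (int ix = 0; ix < nx; ix++) {
      R_xlen_t base = (R_xlen_t)iz * nx * ny + ix;
      for (int iy = 0; iy < ny; iy++) f[iy] = out[base + (R_xlen_t)iy * nx];
      dt1d(f, d, v, z, ny);
      for (int iy = 0; iy < ny; iy++) out[base + (R_xlen_t)iy * nx] = d[iy];
    }
  // z-axis
  for (int iy = 0; iy < ny; iy++)
    for (int ix = 0; ix < nx; ix++) {
      R_xlen_t base = (R_xlen_t)iy * nx + ix;
      for (int iz = 0; iz < nz; iz++)
        f[iz] = out[base + (R_xlen_t)iz * nx * ny];
      dt1d(f, d, v, z, nz);
      for (int iz = 0; iz < nz; iz++)
        out[base + (R_xlen_t)iz * nx * ny] = d[iz];
    }
  return out;
}
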