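#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

// 1D squared distance transform (Felzenszwalb & Huttenlocher), grid step h.
// f: squared distances at sample points; d: output.
static void dt1d(const double* f, double* d, int n, double h) {
  if (n == 1) { d[0] = f[0]; return; }
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double qq = (double)q * h;
    double vv = (double)v[k] * h;
    double s = ((f[q] + qq * qq) - (f[v[k]] + vv * vv)) / (2.0 * (qq - vv));
    while (s <= z[k]) {
      --k;
      vv = (double)v[k] * h;
      s = ((f[q] + qq * qq) - (f[v[k]] + vv * vv)) / (2.0 * (qq - vv));
    }
    ++k; v[k] = q; z[k] = s; z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double qq = (double)q * h;
    while (z[k + 1] < qq) ++k;
    double dd = qq - (double)v[k] * h;
    d[q] = dd * dd + f[v[k]];
  }
}

// Euclidean distance (mm) from every voxel to the nearest TRUE voxel.
// Voxels are indexed on an anisotropic grid with per-axis spacing (mm).
// Returns +Inf everywhere if the mask is empty.
// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector mask, IntegerVector dim,
                      NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  // large finite stand-in for +Inf keeps the envelope intersections finite
  const double BIG = 1e20;
  std::vector<double> g(n);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = mask[i] ? 0.0 : BIG;

  std::vector<double> buf(std::max(nx, std::max(ny, nz)));
  std::vector<double> out(std::max(nx, std::max(ny, nz)));

  // axis 0 (x): contiguous stride 1
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      double* col = &g[(R_xlen_t)z * nx * ny + (R_xlen_t)y * nx];
      dt1d(col, out.data(), nx, spacing[0]);
      std::copy(out.begin(), out.begin() + nx, col);
    }
  // axis 1 (y)
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y)
        buf[y] = g[(R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x];
      dt1d(buf.data(), out.data(), ny, spacing[1]);
      for (int y = 0; y < ny; ++y)
        g[(R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x] = out[y];
    }
  // axis 2 (z)
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      for (int z = 0; z < nz; ++z)
        buf[z] = g[(R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x];
      dt1d(buf.data(), out.data(), nz, spacing[2]);
      for (int z = 0; z < nz; ++z)
        g[(R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x] = out[z];
    }

  NumericVector res(n);
  for (R_xlen_t i = 0; i < n; ++i)
    res[i] = (g[i] >= 1e19) ? R_PosInf : std::sqrt(g[i]);
  return res;
}
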