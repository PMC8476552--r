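// Sub-voxel interface reconstruction from binary label boundaries.
//
// A rasterized segmentation only locates a smooth tissue interface to within
// half a voxel. The routines here recover sub-voxel position by fitting, at
// every boundary voxel, a local quadric patch (moving least squares) through
// the midpoints of the label-change faces in a neighbourhood. The fitted
// patches provide (a) Dirichlet boundary offsets for the Laplace solver and
// (b) a corrected signed-distance band for isosurface extraction.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Solve symmetric 6x6 system in-place (Gaussian elimination, partial pivot).
static bool solve6(double A[6][6], double b[6], double x[6]) {
  int piv[6];
  for (int i = 0; i < 6; ++i) piv[i] = i;
  for (int k = 0; k < 6; ++k) {
    int p = k;
    double best = std::fabs(A[k][k]);
    for (int i = k + 1; i < 6; ++i)
      if (std::fabs(A[i][k]) > best) { best = std::fabs(A[i][k]); p = i; }
    if (best < 1e-14) return false;
    if (p != k) {
      for (int j = 0; j < 6; ++j) std::swap(A[k][j], A[p][j]);
      std::swap(b[k], b[p]);
    }
    for (int i = k + 1; i < 6; ++i) {
      double f = A[i][k] / A[k][k];
      for (int j = k; j < 6; ++j) A[i][j] -= f * A[k][j];
      b[i] -= f * b[k];
    }
  }
  for (int i = 5; i >= 0; --i) {
    double s = b[i];
    for (int j = i + 1; j < 6; ++j) s -= A[i][j] * x[j];
    x[i] = s / A[i][i];
  }
  return true;
}

// Midpoints of faces between TRUE voxels of maskA and TRUE voxels of maskB
// (6-connectivity), in physical mm.
// [[Rcpp::export]]
NumericMatrix cpp_face_cloud(LogicalVector maskA, LogicalVector maskB,
                             IntegerVector dim, NumericVector spacing,
                             NumericVector origin) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  std::vector<double> px, py, pz;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t i = x * sx + y * sy + z * sz;
        if (!maskA[i]) continue;
        if (x + 1 < nx && maskB[i + sx]) {
          px.push_back(origin[0] + (x + 0.5) * spacing[0]);
          py.push_back(origin[1] + y * spacing[1]);
          pz.push_back(origin[2] + z * spacing[2]);
        }
        if (x > 0 && maskB[i - sx]) {
          px.push_back(origin[0] + (x - 0.5) * spacing[0]);
          py.push_back(origin[1] + y * spacing[1]);
          pz.push_back(origin[2] + z * spacing[2]);
        }
        if (y + 1 < ny && maskB[i + sy]) {
          px.push_back(origin[0] + x * spacing[0]);
          py.push_back(origin[1] + (y + 0.5) * spacing[1]);
          pz.push_back(origin[2] + z * spacing[2]);
        }
        if (y > 0 && maskB[i - sy]) {
          px.push_back(origin[0] + x * spacing[0]);
          py.push_back(origin[1] + (y - 0.5) * spacing[1]);
          pz.push_back(origin[2] + z * spacing[2]);
        }
        if (z + 1 < nz && maskB[i + sz]) {
          px.push_back(origin[0] + x * spacing[0]);
          py.push_back(origin[1] + y * spacing[1]);
          pz.push_back(origin[2] + (z + 0.5) * spacing[2]);
        }
        if (z > 0 && maskB[i - sz]) {
          px.push_back(origin[0] + x * spacing[0]);
          py.push_back(origin[1] + y * spacing[1]);
          pz.push_back(origin[2] + (z - 0.5) * spacing[2]);
        }
      }
  const int n = (int)px.size();
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = px[i];
    out(i, 1) = py[i];
    out(i, 2) = pz[i];
  }
  return out;
}

struct HashGrid {
  double cell;
  double mn[3];
  int nc[3];
  std::vector<std::vector<int> > buckets;
  const NumericMatrix* pts;

  void build(const NumericMatrix& p, double cellSize) {
    pts = &p;
    cell = cellSize;
    for (int d = 0; d < 3; ++d) {
      double lo = R_PosInf, hi = R_NegInf;
      for (int i = 0; i < p.nrow(); ++i) {
        if (p(i, d) < lo) lo = p(i, d);
        if (p(i, d) > hi) hi = p(i, d);
      }
      mn[d] = lo;
      nc[d] = std::max(1, (int)std::floor((hi - lo) / cell) + 1);
    }
    buckets.assign((size_t)nc[0] * nc[1] * nc[2], std::vector<int>());
    for (int i = 0; i < p.nrow(); ++i) {
      int cx = (int)((p(i, 0) - mn[0]) / cell);
      int cy = (int)((p(i, 1) - mn[1]) / cell);
      int cz = (int)((p(i, 2) - mn[2]) / cell);
      buckets[(size_t)cz * nc[0] * nc[1] + (size_t)cy * nc[0] + cx]
          .push_back(i);
    }
  }
  template <class F>
  void visit(const double* c, double radius, F fun) const {
    int lo[3], hi[3];
    for (int d = 0; d < 3; ++d) {
      lo[d] = std::max(0, (int)((c[d] - radius - mn[d]) / cell));
      hi[d] = std::min(nc[d] - 1, (int)((c[d] + radius - mn[d]) / cell));
    }
    for (int z = lo[2]; z <= hi[2]; ++z)
      for (int y = lo[1]; y <= hi[1]; ++y)
        for (int x = lo[0]; x <= hi[0]; ++x) {
          const std::vector<int>& b =
              buckets[(size_t)z * nc[0] * nc[1] + (size_t)y * nc[0] + x];
          for (size_t k = 0; k < b.size(); ++k) fun(b[k]);
        }
  }
};

// Weighted quadric fits w = c0 + c1 u + c2 v + c3 u^2 + c4 uv + c5 v^2 of the
// interface cloud in the local frame of each fit center. `normals` point from
// the wall voxel towards the interface.
// Returns coef (m x 6), e1, e2 (m x 3 tangents), ok (m).
// [[Rcpp::export]]
List cpp_quadric_fit(NumericMatrix cloud, NumericMatrix centers,
                     NumericMatrix normals, double sigma_t, double sigma_n) {
  const int m = centers.nrow();
  NumericMatrix coef(m, 6), e1m(m, 3), e2m(m, 3);
  LogicalVector ok(m);
  if (cloud.nrow() == 0) {
    return List::create(_["coef"] = coef, _["e1"] = e1m, _["e2"] = e2m,
                        _["ok"] = ok);
  }
  HashGrid grid;
  grid.build(cloud, sigma_t);
  const double rT = 2.0 * sigma_t, rN = 2.0 * sigma_n;
  const double it2 = 1.0 / (2.0 * sigma_t * sigma_t);
  const double in2 = 1.0 / (2.0 * sigma_n * sigma_n);

  for (int i = 0; i < m; ++i) {
    double n0 = normals(i, 0), n1 = normals(i, 1), n2 = normals(i, 2);
    double nn = std::sqrt(n0 * n0 + n1 * n1 + n2 * n2);
    if (nn < 1e-12) { ok[i] = false; continue; }
    n0 /= nn; n1 /= nn; n2 /= nn;
    // tangent frame: cross normal with least-aligned axis
    double ax = std::fabs(n0), ay = std::fabs(n1), az = std::fabs(n2);
    double a0 = 0, a1 = 0, a2 = 0;
    if (ax <= ay && ax <= az) a0 = 1;
    else if (ay <= az) a1 = 1;
    else a2 = 1;
    double e1x = n1 * a2 - n2 * a1, e1y = n2 * a0 - n0 * a2,
           e1z = n0 * a1 - n1 * a0;
    double en = std::sqrt(e1x * e1x + e1y * e1y + e1z * e1z);
    e1x /= en; e1y /= en; e1z /= en;
    double e2x = n1 * e1z - n2 * e1y, e2y = n2 * e1x - n0 * e1z,
           e2z = n0 * e1y - n1 * e1x;

    double AtA[6][6] = {{0}}, Atb[6] = {0};
    int npt = 0;
    const double c0 = centers(i, 0), c1 = centers(i, 1), c2 = centers(i, 2);
    double cc[3] = {c0, c1, c2};
    grid.visit(cc, rT, [&](int j) {
      double dx = cloud(j, 0) - c0, dy = cloud(j, 1) - c1,
             dz = cloud(j, 2) - c2;
      double u = dx * e1x + dy * e1y + dz * e1z;
      double v = dx * e2x + dy * e2y + dz * e2z;
      double w = dx * n0 + dy * n1 + dz * n2;
      double t2 = u * u + v * v;
      if (t2 > rT * rT || std::fabs(w) > rN) return;
      double wt = std::exp(-t2 * it2 - w * w * in2);
      double basis[6] = {1.0, u, v, u * u, u * v, v * v};
      for (int a = 0; a < 6; ++a) {
        for (int b = a; b < 6; ++b) AtA[a][b] += wt * basis[a] * basis[b];
        Atb[a] += wt * basis[a] * w;
      }
      ++npt;
    });
    if (npt < 8) { ok[i] = false; continue; }
    for (int a = 0; a < 6; ++a) {
      for (int b = 0; b < a; ++b) AtA[a][b] = AtA[b][a];
      AtA[a][a] += 1e-9 * AtA[0][0] + 1e-12;
    }
    double x[6];
    if (!solve6(AtA, Atb, x)) { ok[i] = false; continue; }
    for (int a = 0; a < 6; ++a) coef(i, a) = x[a];
    e1m(i, 0) = e1x; e1m(i, 1) = e1y; e1m(i, 2) = e1z;
    e2m(i, 0) = e2x; e2m(i, 1) = e2y; e2m(i, 2) = e2z;
    ok[i] = true;
  }
  return List::create(_["coef"] = coef, _["e1"] = e1m, _["e2"] = e2m,
                      _["ok"] = ok);
}

// Fractional crossing of the fitted interface along axis arms.
// For arm k the line is p(t) = centers[fitIdx[k]] + t * len[k] * dir[k],
// t in [0,1]; returns the crossing t (clamped to [minTheta, 1]) or 0.5 when
// the fit is invalid or no root lies in [0, 1.2].
// [[Rcpp::export]]
NumericVector cpp_arm_theta(NumericMatrix centers, NumericMatrix normals,
                            List fit, IntegerVector fitIdx, NumericMatrix dir,
                            NumericVector len, double minTheta) {
  NumericMatrix coef = fit["coef"], e1 = fit["e1"], e2 = fit["e2"];
  LogicalVector ok = fit["ok"];
  const int n = fitIdx.size();
  NumericVector theta(n);
  for (int k = 0; k < n; ++k) {
    int i = fitIdx[k] - 1;
    double th = 0.5;
    if (ok[i]) {
      double nx = normals(i, 0), ny = normals(i, 1), nz = normals(i, 2);
      double nn = std::sqrt(nx * nx + ny * ny + nz * nz);
      nx /= nn; ny /= nn; nz /= nn;
      double dx = dir(k, 0) * len[k], dy = dir(k, 1) * len[k],
             dz = dir(k, 2) * len[k];
      // local coords of the line: p(t) - center = t * d
      double du = dx * e1(i, 0) + dy * e1(i, 1) + dz * e1(i, 2);
      double dv = dx * e2(i, 0) + dy * e2(i, 1) + dz * e2(i, 2);
      double dw = dx * nx + dy * ny + dz * nz;
      // g(t) = w(t) - q(u(t), v(t)) with u=du*t, v=dv*t, w=dw*t
      const double c0 = coef(i, 0), c1 = coef(i, 1), c2 = coef(i, 2),
                   c3 = coef(i, 3), c4 = coef(i, 4), c5 = coef(i, 5);
      double A = -(c3 * du * du + c4 * du * dv + c5 * dv * dv);
      double B = dw - c1 * du - c2 * dv;
      double C = -c0;
      double root = -1.0;
      if (std::fabs(A) < 1e-12 * std::fabs(B) + 1e-300) {
        if (B != 0.0) root = -C / B;
      } else {
        double disc = B * B - 4.0 * A * C;
        if (disc >= 0.0) {
          double sq = std::sqrt(disc);
          double r1 = (-B - sq) / (2.0 * A), r2 = (-B + sq) / (2.0 * A);
          if (r1 > r2) std::swap(r1, r2);
          // smallest root in [-0.2, 1.2]
          if (r1 >= -0.2 && r1 <= 1.2) root = r1;
          else if (r2 >= -0.2 && r2 <= 1.2) root = r2;
        }
      }
      if (root >= -0.2 && root <= 1.2) th = root;
    }
    if (th < minTheta) th = minTheta;
    if (th > 1.0) th = 1.0;
    theta[k] = th;
  }
  return theta;
}

// Signed offset of query points from the fitted interface, using the fit of
// the nearest center voxel (searched in a window of the center-index grid).
// centerGrid: per-voxel fit index (1-based) or 0; queries are voxel linear
// indices (1-based). Positive = beyond the interface (region side).
// Returns NA where no center is found nearby.
// [[Rcpp::export]]
NumericVector cpp_band_phi(IntegerVector centerGrid, IntegerVector dim,
                           NumericVector spacing, NumericVector origin,
                           IntegerVector queries, NumericMatrix centers,
                           NumericMatrix normals, List fit, int window) {
  NumericMatrix coef = fit["coef"], e1 = fit["e1"], e2 = fit["e2"];
  LogicalVector ok = fit["ok"];
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int nq = queries.size();
  NumericVector out(nq);
  for (int q = 0; q < nq; ++q) {
    R_xlen_t lin = (R_xlen_t)queries[q] - 1;
    int x = (int)(lin % nx);
    int y = (int)((lin / nx) % ny);
    int z = (int)(lin / ((R_xlen_t)nx * ny));
    double qx = origin[0] + x * spacing[0];
    double qy = origin[1] + y * spacing[1];
    double qz = origin[2] + z * spacing[2];
    int best = -1;
    double bestd = R_PosInf;
    for (int dz = -window; dz <= window; ++dz) {
      int zz = z + dz;
      if (zz < 0 || zz >= nz) continue;
      for (int dy = -window; dy <= window; ++dy) {
        int yy = y + dy;
        if (yy < 0 || yy >= ny) continue;
        for (int dx = -window; dx <= window; ++dx) {
          int xx = x + dx;
          if (xx < 0 || xx >= nx) continue;
          R_xlen_t l2 = xx + (R_xlen_t)yy * nx + (R_xlen_t)zz * nx * ny;
          int ci = centerGrid[l2];
          if (ci <= 0 || !ok[ci - 1]) continue;
          double d2 = dx * spacing[0] * dx * spacing[0] +
                      dy * spacing[1] * dy * spacing[1] +
                      dz * spacing[2] * dz * spacing[2];
          if (d2 < bestd) { bestd = d2; best = ci - 1; }
        }
      }
    }
    if (best < 0) { out[q] = NA_REAL; continue; }
    int i = best;
    double nx0 = normals(i, 0), ny0 = normals(i, 1), nz0 = normals(i, 2);
    double nn = std::sqrt(nx0 * nx0 + ny0 * ny0 + nz0 * nz0);
    nx0 /= nn; ny0 /= nn; nz0 /= nn;
    double dx = qx - centers(i, 0), dy = qy - centers(i, 1),
           dz = qz - centers(i, 2);
    double u = dx * e1(i, 0) + dy * e1(i, 1) + dz * e1(i, 2);
    double v = dx * e2(i, 0) + dy * e2(i, 1) + dz * e2(i, 2);
    double w = dx * nx0 + dy * ny0 + dz * nz0;
    out[q] = w - (coef(i, 0) + coef(i, 1) * u + coef(i, 2) * v +
                  coef(i, 3) * u * u + coef(i, 4) * u * v +
                  coef(i, 5) * v * v);
  }
  return out;
}
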