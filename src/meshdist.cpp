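#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Squared distance from point p to triangle (a, b, c)
// (Ericson, Real-Time Collision Detection, closest-point formulation).
static double pointTriDist2(const double* p, const double* a, const double* b,
                            const double* c) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i];
    ac[i] = c[i] - a[i];
    ap[i] = p[i] - a[i];
  }
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  double q[3];
  if (d1 <= 0.0 && d2 <= 0.0) {
    q[0] = a[0]; q[1] = a[1]; q[2] = a[2];
  } else {
    double bp[3] = {p[0] - b[0], p[1] - b[1], p[2] - b[2]};
    double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
    double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
    if (d3 >= 0.0 && d4 <= d3) {
      q[0] = b[0]; q[1] = b[1]; q[2] = b[2];
    } else {
      double vc = d1 * d4 - d3 * d2;
      if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
        double t = d1 / (d1 - d3);
        for (int i = 0; i < 3; ++i) q[i] = a[i] + t * ab[i];
      } else {
        double cp[3] = {p[0] - c[0], p[1] - c[1], p[2] - c[2]};
        double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
        double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
        if (d6 >= 0.0 && d5 <= d6) {
          q[0] = c[0]; q[1] = c[1]; q[2] = c[2];
        } else {
          double vb = d5 * d2 - d1 * d6;
          if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
            double t = d2 / (d2 - d6);
            for (int i = 0; i < 3; ++i) q[i] = a[i] + t * ac[i];
          } else {
            double va = d3 * d6 - d5 * d4;
            if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
              double t = (d4 - d3) / ((d4 - d3) + (d5 - d6));
              for (int i = 0; i < 3; ++i) q[i] = b[i] + t * (c[i] - b[i]);
            } else {
              double denom = 1.0 / (va + vb + vc);
              double v = vb * denom, w = vc * denom;
              for (int i = 0; i < 3; ++i)
                q[i] = a[i] + ab[i] * v + ac[i] * w;
            }
          }
        }
      }
    }
  }
  double dx = p[0] - q[0], dy = p[1] - q[1], dz = p[2] - q[2];
  return dx * dx + dy * dy + dz * dz;
}

// Minimum distance from each point to a triangle mesh, with a
// centroid-radius lower bound to prune the triangle loop.
// [[Rcpp::export]]
NumericVector cpp_point_mesh_dist(NumericMatrix pts, NumericMatrix verts,
                                  IntegerMatrix faces) {
  const int np = pts.nrow(), nt = faces.nrow();
  std::vector<double> cx(nt), cy(nt), cz(nt), rad(nt);
  std::vector<double> va(3 * nt), vb(3 * nt), vc(3 * nt);
  for (int t = 0; t < nt; ++t) {
    int ia = faces(t, 0) - 1, ib = faces(t, 1) - 1, ic = faces(t, 2) - 1;
    for (int d = 0; d < 3; ++d) {
      va[3 * t + d] = verts(ia, d);
      vb[3 * t + d] = verts(ib, d);
      vc[3 * t + d] = verts(ic, d);
    }
    cx[t] = (va[3 * t] + vb[3 * t] + vc[3 * t]) / 3.0;
    cy[t] = (va[3 * t + 1] + vb[3 * t + 1] + vc[3 * t + 1]) / 3.0;
    cz[t] = (va[3 * t + 2] + vb[3 * t + 2] + vc[3 * t + 2]) / 3.0;
    double r2 = 0;
    for (int k = 0; k < 3; ++k) {
      const double* v = (k == 0) ? &va[3 * t] : (k == 1) ? &vb[3 * t]
                                                         : &vc[3 * t];
      double dx = v[0] - cx[t], dy = v[1] - cy[t], dz = v[2] - cz[t];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > r2) r2 = d2;
    }
    rad[t] = std::sqrt(r2);
  }
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    double pt[3] = {pts(p, 0), pts(p, 1), pts(p, 2)};
    double best = R_PosInf;
    for (int t = 0; t < nt; ++t) {
      double dx = pt[0] - cx[t], dy = pt[1] - cy[t], dz = pt[2] - cz[t];
      double lb = std::sqrt(dx * dx + dy * dy + dz * dz) - rad[t];
      if (lb * lb >= best && lb > 0) continue;
      double d2 = pointTriDist2(pt, &va[3 * t], &vb[3 * t], &vc[3 * t]);
      if (d2 < best) best = d2;
    }
    out[p] = std::sqrt(best);
  }
  return out;
}

// Index (1-based) of the nearest row of B for each row of A.
// [[Rcpp::export]]
IntegerVector cpp_nearest_point(NumericMatrix A, NumericMatrix B) {
  const int na = A.nrow(), nb = B.nrow();
  IntegerVector out(na);
  for (int i = 0; i < na; ++i) {
    double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
    double best = R_PosInf;
    int bi = 1;
    for (int j = 0; j < nb; ++j) {
      double dx = ax - B(j, 0), dy = ay - B(j, 1), dz = az - B(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) { best = d2; bi = j + 1; }
    }
    out[i] = bi;
  }
  return out;
}
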