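#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include "mc_tables.h"

using namespace Rcpp;

// Cube corner offsets (Lorensen & Cline numbering).
static const int cornerOff[8][3] = {
  {0, 0, 0}, {1, 0, 0}, {1, 1, 0}, {0, 1, 0},
  {0, 0, 1}, {1, 0, 1}, {1, 1, 1}, {0, 1, 1}
};
// Edge -> corner pair.
static const int edgeCorner[12][2] = {
  {0, 1}, {1, 2}, {2, 3}, {3, 0},
  {4, 5}, {5, 6}, {6, 7}, {7, 4},
  {0, 4}, {1, 5}, {2, 6}, {3, 7}
};

// Isosurface of a scalar field at `level`, vertices in physical mm
// (origin + index * spacing). Inside = field value < level.
// Cells containing non-finite values are skipped.
// [[Rcpp::export]]
List cpp_marching_cubes(NumericVector field, IntegerVector dim,
                        NumericVector spacing, NumericVector origin,
                        double level) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;

  std::vector<double> vx, vy, vzc;
  std::vector<int> tri;
  std::unordered_map<long long, int> edgeVert;
  edgeVert.reserve(1 << 16);

  double corner[8];
  R_xlen_t cid[8];

  auto edgeKey = [&](int x, int y, int z, int edge) -> long long {
    // canonical edge id: anchored voxel + axis
    int ax, bx = x, by = y, bz = z;
    switch (edge) {
      case 0:  ax = 0; break;
      case 1:  ax = 1; bx += 1; break;
      case 2:  ax = 0; by += 1; break;
      case 3:  ax = 1; break;
      case 4:  ax = 0; bz += 1; break;
      case 5:  ax = 1; bx += 1; bz += 1; break;
      case 6:  ax = 0; by += 1; bz += 1; break;
      case 7:  ax = 1; bz += 1; break;
      case 8:  ax = 2; break;
      case 9:  ax = 2; bx += 1; break;
      case 10: ax = 2; bx += 1; by += 1; break;
      case 11: ax = 2; by += 1; break;
      default: ax = 0;
    }
    long long lin = (long long)bz * nx * ny + (long long)by * nx + bx;
    return lin * 3 + ax;
  };

  for (int z = 0; z < nz - 1; ++z)
    for (int y = 0; y < ny - 1; ++y)
      for (int x = 0; x < nx - 1; ++x) {
        int cube = 0;
        bool bad = false;
        for (int c = 0; c < 8; ++c) {
          cid[c] = (x + cornerOff[c][0]) * sx + (y + cornerOff[c][1]) * sy +
                   (R_xlen_t)(z + cornerOff[c][2]) * sz;
          corner[c] = field[cid[c]];
          if (!std::isfinite(corner[c])) { bad = true; break; }
          if (corner[c] < level) cube |= (1 << c);
        }
        if (bad || mcEdgeTable[cube] == 0) continue;

        int ev[12];
        for (int e = 0; e < 12; ++e) {
          if (!(mcEdgeTable[cube] & (1 << e))) continue;
          long long key = edgeKey(x, y, z, e);
          auto it = edgeVert.find(key);
          if (it != edgeVert.end()) { ev[e] = it->second; continue; }
          int c1 = edgeCorner[e][0], c2 = edgeCorner[e][1];
          double v1 = corner[c1], v2 = corner[c2];
          double t = (v2 != v1) ? (level - v1) / (v2 - v1) : 0.5;
          if (t < 0.0) t = 0.0;
          if (t > 1.0) t = 1.0;
          double px = x + cornerOff[c1][0] +
                      t * (cornerOff[c2][0] - cornerOff[c1][0]);
          double py = y + cornerOff[c1][1] +
                      t * (cornerOff[c2][1] - cornerOff[c1][1]);
          double pz = z + cornerOff[c1][2] +
                      t * (cornerOff[c2][2] - cornerOff[c1][2]);
          int vi = (int)vx.size();
          vx.push_back(origin[0] + px * spacing[0]);
          vy.push_back(origin[1] + py * spacing[1]);
          vzc.push_back(origin[2] + pz * spacing[2]);
          edgeVert[key] = vi;
          ev[e] = vi;
        }

        const signed char* tt = mcTriTable[cube];
        for (int i = 0; tt[i] != -1; i += 3) {
          tri.push_back(ev[(int)tt[i]]);
          tri.push_back(ev[(int)tt[i + 1]]);
          tri.push_back(ev[(int)tt[i + 2]]);
        }
      }

  const int nv = (int)vx.size();
  NumericMatrix verts(nv, 3);
  for (int i = 0; i < nv; ++i) {
    verts(i, 0) = vx[i];
    verts(i, 1) = vy[i];
    verts(i, 2) = vzc[i];
  }
  const int nt = (int)tri.size() / 3;
  IntegerMatrix faces(nt, 3);
  for (int i = 0; i < nt; ++i) {
    faces(i, 0) = tri[3 * i] + 1;      // 1-based for R
    faces(i, 1) = tri[3 * i + 1] + 1;
    faces(i, 2) = tri[3 * i + 2] + 1;
  }
  return List::create(_["vertices"] = verts, _["faces"] = faces);
}
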