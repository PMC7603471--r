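// Isosurface extraction from a binary mask by marching tetrahedra (6-tet cube
// decomposition, iso-level 0.5, vertices at lattice-edge midpoints), with a
// virtual zero ghost layer so meshes are closed even when a structure touches
// the volume boundary.  Vertices are welded exactly (midpoint lattice keys).
#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

namespace {

struct V3 { double x, y, z; };

// 6-tet decomposition of the unit cube, all sharing diagonal c0-c7.
// corner bits: (i, j, k) -> i + 2j + 4k
const int TETS[6][4] = {
  {0, 5, 1, 7}, {0, 1, 3, 7}, {0, 3, 2, 7},
  {0, 2, 6, 7}, {0, 6, 4, 7}, {0, 4, 5, 7}
};

struct Builder {
  std::unordered_map<int64_t, int> vmap;
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;
  int64_t nx2, ny2;

  // vertex at midpoint of lattice points a, b (doubled-integer coordinates)
  int vertex(const int a[3], const int b[3], const double* sp, const double* org) {
    int64_t cx = a[0] + b[0] + 2, cy = a[1] + b[1] + 2, cz = a[2] + b[2] + 2;  // *2, shifted +2 to stay >=0
    int64_t key = (cz * ny2 + cy) * nx2 + cx;
    auto it = vmap.find(key);
    if (it != vmap.end()) return it->second;
    int id = (int)vx.size();
    vmap[key] = id;
    vx.push_back(org[0] + 0.5 * (a[0] + b[0]) * sp[0]);
    vy.push_back(org[1] + 0.5 * (a[1] + b[1]) * sp[1]);
    vz.push_back(org[2] + 0.5 * (a[2] + b[2]) * sp[2]);
    return id;
  }

  void emit(int i, int j, int k, const double* inC, const double* outC) {
    // orient outward: normal should point from inside centroid to outside centroid
    double ax = vx[j] - vx[i], ay = vy[j] - vy[i], az = vz[j] - vz[i];
    double bx = vx[k] - vx[i], by = vy[k] - vy[i], bz = vz[k] - vz[i];
    double nxv = ay * bz - az * by, nyv = az * bx - ax * bz, nzv = ax * by - ay * bx;
    double dx = outC[0] - inC[0], dy = outC[1] - inC[1], dz = outC[2] - inC[2];
    if (nxv * dx + nyv * dy + nzv * dz >= 0) {
      tri.push_back(i); tri.push_back(j); tri.push_back(k);
    } else {
      tri.push_back(i); tri.push_back(k); tri.push_back(j);
    }
  }
};

}  // namespace

// [[Rcpp::export]]
List march_tets_cpp(IntegerVector mask, IntegerVector dims,
                    NumericVector spacing, NumericVector origin) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  double sp[3] = {spacing[0], spacing[1], spacing[2]};
  double org[3] = {origin[0], origin[1], origin[2]};
  Builder B;
  B.nx2 = 2 * (int64_t)(nx + 2);
  B.ny2 = 2 * (int64_t)(ny + 2);

  auto val = [&](int i, int j, int k) -> int {
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return 0;
    return mask[(int64_t)k * nx * ny + (int64_t)j * nx + i] != 0 ? 1 : 0;
  };

  int corner[8][3];
  for (int c = 0; c < 8; c++) {
    corner[c][0] = c & 1; corner[c][1] = (c >> 1) & 1; corner[c][2] = (c >> 2) & 1;
  }

  for (int k = -1; k < nz; k++)
    for (int j = -1; j < ny; j++)
      for (int i = -1; i < nx; i++) {
        int v[8];
        int sum = 0;
        for (int c = 0; c < 8; c++) {
          v[c] = val(i + corner[c][0], j + corner[c][1], k + corner[c][2]);
          sum += v[c];
        }
        if (sum == 0 || sum == 8) continue;
        for (int t = 0; t < 6; t++) {
          int tv[4], ins = 0;
          int tc[4][3];
          for (int q = 0; q < 4; q++) {
            int c = TETS[t][q];
            tv[q] = v[c];
            ins += tv[q];
            tc[q][0] = i + corner[c][0];
            tc[q][1] = j + corner[c][1];
            tc[q][2] = k + corner[c][2];
          }
          if (ins == 0 || ins == 4) continue;
          // centroids of inside / outside tet corners (physical coords)
          double inC[3] = {0, 0, 0}, outC[3] = {0, 0, 0};
          int nin = 0, nout = 0;
          for (int q = 0; q < 4; q++) {
            double px = org[0] + tc[q][0] * sp[0];
            double py = org[1] + tc[q][1] * sp[1];
            double pz = org[2] + tc[q][2] * sp[2];
            if (tv[q]) { inC[0] += px; inC[1] += py; inC[2] += pz; nin++; }
            else { outC[0] += px; outC[1] += py; outC[2] += pz; nout++; }
          }
          for (int a = 0; a < 3; a++) { inC[a] /= nin; outC[a] /= nout; }
          if (ins == 1 || ins == 3) {
            int apex = -1;
            for (int q = 0; q < 4; q++)
              if ((ins == 1 && tv[q] == 1) || (ins == 3 && tv[q] == 0)) apex = q;
            int o[3], m = 0;
            for (int q = 0; q < 4; q++) if (q != apex) o[m++] = q;
            int a0 = B.vertex(tc[apex], tc[o[0]], sp, org);
            int a1 = B.vertex(tc[apex], tc[o[1]], sp, org);
            int a2 = B.vertex(tc[apex], tc[o[2]], sp, org);
            B.emit(a0, a1, a2, inC, outC);
          } else {  // 2-2 case: quad split into two triangles
            int inI[2], outI[2], mi = 0, mo = 0;
            for (int q = 0; q < 4; q++) {
              if (tv[q]) inI[mi++] = q; else outI[mo++] = q;
            }
            int p00 = B.vertex(tc[inI[0]], tc[outI[0]], sp, org);
            int p01 = B.vertex(tc[inI[0]], tc[outI[1]], sp, org);
            int p10 = B.vertex(tc[inI[1]], tc[outI[0]], sp, org);
            int p11 = B.vertex(tc[inI[1]], tc[outI[1]], sp, org);
            B.emit(p00, p01, p11, inC, outC);
            B.emit(p00, p11, p10, inC, outC);
          }
        }
      }

  int nvert = (int)B.vx.size();
  NumericMatrix V(nvert, 3);
  for (int q = 0; q < nvert; q++) {
    V(q, 0) = B.vx[q]; V(q, 1) = B.vy[q]; V(q, 2) = B.vz[q];
  }
  int nt = (int)B.tri.size() / 3;
  IntegerMatrix F(nt, 3);
  for (int q = 0; q < nt; q++) {
    F(q, 0) = B.tri[3 * q] + 1;
    F(q, 1) = B.tri[3 * q + 1] + 1;
    F(q, 2) = B.tri[3 * q + 2] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}
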