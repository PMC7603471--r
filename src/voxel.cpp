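// Voxel-grid operations: 26-connected component labelling, anisotropic
// 3D morphology, surface-voxel extraction, Hausdorff distance between voxel
// surfaces, and analytic rasterizers (capsule tubes with varying radius,
// ellipsoid shells) used by the synthetic anatomy generator.
#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

// Label 26-connected components in scan order; component ids are assigned by
// the (column-major) scan index of their seed voxel, so ties in size resolve
// deterministically to the component seeded earliest.
// [[Rcpp::export]]
List cc_label_cpp(IntegerVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int64_t n = (int64_t)nx * ny * nz;
  IntegerVector lab(n);
  std::vector<int> sizes;
  std::vector<int64_t> stack;
  int cur = 0;
  for (int64_t s = 0; s < n; s++) {
    if (mask[s] == 0 || lab[s] != 0) continue;
    cur++;
    int sz = 0;
    stack.clear();
    stack.push_back(s);
    lab[s] = cur;
    while (!stack.empty()) {
      int64_t p = stack.back();
      stack.pop_back();
      sz++;
      int i = (int)(p % nx), j = (int)((p / nx) % ny), k = (int)(p / ((int64_t)nx * ny));
      for (int dk = -1; dk <= 1; dk++)
        for (int dj = -1; dj <= 1; dj++)
          for (int di = -1; di <= 1; di++) {
            if (di == 0 && dj == 0 && dk == 0) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
            int64_t q = (int64_t)kk * nx * ny + (int64_t)jj * nx + ii;
            if (mask[q] != 0 && lab[q] == 0) { lab[q] = cur; stack.push_back(q); }
          }
    }
    sizes.push_back(sz);
  }
  return List::create(_["labels"] = lab, _["sizes"] = wrap(sizes));
}

// Ellipsoidal structuring element with semi-axes (rx, ry, rz) in voxels.
// [[Rcpp::export]]
IntegerVector morph_cpp(IntegerVector mask, IntegerVector dims,
                        NumericVector radii, bool dilate) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  double rx = std::max(radii[0], 1e-9), ry = std::max(radii[1], 1e-9),
         rz = std::max(radii[2], 1e-9);
  int mx = (int)std::floor(rx), my = (int)std::floor(ry), mz = (int)std::floor(rz);
  std::vector<int> off;
  for (int dk = -mz; dk <= mz; dk++)
    for (int dj = -my; dj <= my; dj++)
      for (int di = -mx; di <= mx; di++) {
        double q = (di / rx) * (di / rx) + (dj / ry) * (dj / ry) + (dk / rz) * (dk / rz);
        if (q <= 1.0 + 1e-12) { off.push_back(di); off.push_back(dj); off.push_back(dk); }
      }
  int64_t n = (int64_t)nx * ny * nz;
  IntegerVector out(n);
  for (int64_t p = 0; p < n; p++) {
    int i = (int)(p % nx), j = (int)((p / nx) % ny), k = (int)(p / ((int64_t)nx * ny));
    bool hit = dilate ? false : true;
    for (size_t o = 0; o < off.size(); o += 3) {
      int ii = i + off[o], jj = j + off[o + 1], kk = k + off[o + 2];
      int v = 0;
      if (ii >= 0 && jj >= 0 && kk >= 0 && ii < nx && jj < ny && kk < nz)
        v = mask[(int64_t)kk * nx * ny + (int64_t)jj * nx + ii] != 0;
      if (dilate) { if (v) { hit = true; break; } }
      else { if (!v) { hit = false; break; } }
    }
    out[p] = hit ? 1 : 0;
  }
  return out;
}

// Voxels of the mask with at least one 6-neighbour outside the mask
// (out-of-grid counts as outside).  Returns 1-based (i, j, k) indices.
// [[Rcpp::export]]
IntegerMatrix surface_voxels_cpp(IntegerVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int64_t n = (int64_t)nx * ny * nz;
  std::vector<int> res;
  const int d6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  for (int64_t p = 0; p < n; p++) {
    if (mask[p] == 0) continue;
    int i = (int)(p % nx), j = (int)((p / nx) % ny), k = (int)(p / ((int64_t)nx * ny));
    bool surf = false;
    for (int d = 0; d < 6; d++) {
      int ii = i + d6[d][0], jj = j + d6[d][1], kk = k + d6[d][2];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz ||
          mask[(int64_t)kk * nx * ny + (int64_t)jj * nx + ii] == 0) {
        surf = true;
        break;
      }
    }
    if (surf) { res.push_back(i + 1); res.push_back(j + 1); res.push_back(k + 1); }
  }
  int m = (int)res.size() / 3;
  IntegerMatrix out(m, 3);
  for (int q = 0; q < m; q++) {
    out(q, 0) = res[3 * q]; out(q, 1) = res[3 * q + 1]; out(q, 2) = res[3 * q + 2];
  }
  return out;
}

// Classical (max) symmetric Hausdorff distance between two point sets (mm).
// [[Rcpp::export]]
double hausdorff_points_cpp(NumericMatrix A, NumericMatrix B) {
  int na = A.nrow(), nb = B.nrow();
  double h = 0;
  for (int pass = 0; pass < 2; pass++) {
    const NumericMatrix& P = pass == 0 ? A : B;
    const NumericMatrix& Q = pass == 0 ? B : A;
    int np = P.nrow(), nq = Q.nrow();
    for (int i = 0; i < np; i++) {
      double best = 1e300;
      double px = P(i, 0), py = P(i, 1), pz = P(i, 2);
      for (int j = 0; j < nq; j++) {
        double dx = px - Q(j, 0), dy = py - Q(j, 1), dz = pz - Q(j, 2);
        double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 < best) {
          best = d2;
          if (best <= h * h) break;  // cannot raise the running max
        }
      }
      if (best > h * h && best < 1e300) h = std::sqrt(best);
    }
    (void)na; (void)nb;
  }
  return h;
}

// Rasterize a capsule chain (polyline with per-vertex radius, linearly
// interpolated along segments; a single point gives a sphere).  Writes
// `label` into voxels whose centre lies within the tube, but only where the
// volume is still 0 (earlier structures take priority).  In-place.
// [[Rcpp::export]]
void raster_tube_cpp(IntegerVector vol, IntegerVector dims, NumericVector spacing,
                     NumericVector origin, NumericMatrix path, NumericVector radii,
                     int label) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  double ox = origin[0], oy = origin[1], oz = origin[2];
  int np = path.nrow();
  int nseg = std::max(1, np - 1);
  for (int s = 0; s < nseg; s++) {
    int a = s, b = (np == 1) ? s : s + 1;
    double ax = path(a, 0), ay = path(a, 1), az = path(a, 2);
    double bx = path(b, 0), by = path(b, 1), bz = path(b, 2);
    double ra = radii[a], rb = radii[b];
    double rmax = std::max(ra, rb);
    double lo[3] = {std::min(ax, bx) - rmax, std::min(ay, by) - rmax, std::min(az, bz) - rmax};
    double hi[3] = {std::max(ax, bx) + rmax, std::max(ay, by) + rmax, std::max(az, bz) + rmax};
    int i0 = std::max(0, (int)std::floor((lo[0] - ox) / sx));
    int i1 = std::min(nx - 1, (int)std::ceil((hi[0] - ox) / sx));
    int j0 = std::max(0, (int)std::floor((lo[1] - oy) / sy));
    int j1 = std::min(ny - 1, (int)std::ceil((hi[1] - oy) / sy));
    int k0 = std::max(0, (int)std::floor((lo[2] - oz) / sz));
    int k1 = std::min(nz - 1, (int)std::ceil((hi[2] - oz) / sz));
    double ux = bx - ax, uy = by - ay, uz = bz - az;
    double L2 = ux * ux + uy * uy + uz * uz;
    for (int k = k0; k <= k1; k++)
      for (int j = j0; j <= j1; j++)
        for (int i = i0; i <= i1; i++) {
          int64_t p = (int64_t)k * nx * ny + (int64_t)j * nx + i;
          if (vol[p] != 0) continue;
          double px = ox + i * sx, py = oy + j * sy, pz = oz + k * sz;
          double t = 0;
          if (L2 > 0) {
            t = ((px - ax) * ux + (py - ay) * uy + (pz - az) * uz) / L2;
            t = std::max(0.0, std::min(1.0, t));
          }
          double cx = ax + t * ux, cy = ay + t * uy, cz = az + t * uz;
          double r = ra + t * (rb - ra);
          double dx = px - cx, dy = py - cy, dz = pz - cz;
          if (dx * dx + dy * dy + dz * dz <= r * r) vol[p] = label;
        }
  }
}

// Ellipsoid shell of given centre, semi-axes and (approximate) thickness.
// [[Rcpp::export]]
void raster_shell_cpp(IntegerVector vol, IntegerVector dims, NumericVector spacing,
                      NumericVector origin, NumericVector centre, NumericVector semi,
                      double thickness, int label) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  double rbar = (semi[0] + semi[1] + semi[2]) / 3.0;
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        int64_t p = (int64_t)k * nx * ny + (int64_t)j * nx + i;
        if (vol[p] != 0) continue;
        double x = (origin[0] + i * spacing[0] - centre[0]) / semi[0];
        double y = (origin[1] + j * spacing[1] - centre[1]) / semi[1];
        double z = (origin[2] + k * spacing[2] - centre[2]) / semi[2];
        double f = std::sqrt(x * x + y * y + z * z);
        if (std::fabs((f - 1.0) * rbar) <= thickness / 2.0) vol[p] = label;
      }
}
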