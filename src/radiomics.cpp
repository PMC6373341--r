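#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Grey-level run-length counting along one direction.
// q: 3D integer array (levels 1..ng inside the ROI, 0 outside); runs break
// at any non-ROI voxel. A run is maximal: counting starts only at voxels
// with no in-ROI same-direction predecessor of the same level.
// [[Rcpp::export]]
IntegerMatrix cpp_glrlm(IntegerVector q, int ng, int dx, int dy, int dz) {
  IntegerVector dims = q.attr("dim");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  if (dx == 0 && dy == 0 && dz == 0) stop("zero direction");
  const int maxlen = nx + ny + nz;  // safe bound on any run length
  IntegerMatrix counts(ng, maxlen);
  auto at = [&](int x, int y, int z) -> int {
    return q[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)];
  };
  auto inb = [&](int x, int y, int z) -> bool {
    return x >= 0 && x < nx && y >= 0 && y < ny && z >= 0 && z < nz;
  };
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int lev = at(x, y, z);
        if (lev == 0) continue;
        // start of a run iff predecessor is out of bounds, non-ROI, or a
        // different level
        int px = x - dx, py = y - dy, pz = z - dz;
        if (inb(px, py, pz) && at(px, py, pz) == lev) continue;
        int len = 1;
        int cx = x + dx, cy = y + dy, cz = z + dz;
        while (inb(cx, cy, cz) && at(cx, cy, cz) == lev) {
          ++len;
          cx += dx; cy += dy; cz += dz;
        }
        counts(lev - 1, len - 1) += 1;
      }
  return counts;
}

static inline void interp(const double *p, const double *qv,
                          double va, double vb, double level, double *out) {
  double t = (level - va) / (vb - va);
  out[0] = p[0] + t * (qv[0] - p[0]);
  out[1] = p[1] + t * (qv[1] - p[1]);
  out[2] = p[2] + t * (qv[2] - p[2]);
}

static inline double tri_area(const double *a, const double *b, const double *c) {
  double u[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  double v[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
  double w[3] = {u[1] * v[2] - u[2] * v[1],
                 u[2] * v[0] - u[0] * v[2],
                 u[0] * v[1] - u[1] * v[0]};
  return 0.5 * std::sqrt(w[0] * w[0] + w[1] * w[1] + w[2] * w[2]);
}

// Iso-surface area of a scalar field at `level` by marching tetrahedra
// (each grid cell split into 6 tetrahedra, vertices linearly interpolated
// along edges). The field must already be zero-padded so the surface closes.
// [[Rcpp::export]]
double cpp_mesh_area(NumericVector field, NumericVector spacing, double level) {
  IntegerVector dims = field.attr("dim");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  // cube corner offsets and a 6-tetra decomposition sharing diagonal 0-6
  static const int corner[8][3] = {
    {0,0,0},{1,0,0},{1,1,0},{0,1,0},{0,0,1},{1,0,1},{1,1,1},{0,1,1}};
  static const int tet[6][4] = {
    {0,1,2,6},{0,2,3,6},{0,3,7,6},{0,7,4,6},{0,4,5,6},{0,5,1,6}};
  auto at = [&](int x, int y, int z) -> double {
    return field[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)];
  };
  double total = 0.0;
  double cv[8], cp[8][3];
  for (int z = 0; z + 1 < nz; ++z)
    for (int y = 0; y + 1 < ny; ++y)
      for (int x = 0; x + 1 < nx; ++x) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          cv[c] = at(x + corner[c][0], y + corner[c][1], z + corner[c][2]);
          (cv[c] > level ? any_in : any_out) = true;
          cp[c][0] = (x + corner[c][0]) * sx;
          cp[c][1] = (y + corner[c][1]) * sy;
          cp[c][2] = (z + corner[c][2]) * sz;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          int ins[4], outs[4], ni = 0, no = 0;
          for (int c = 0; c < 4; ++c) {
            if (cv[tet[t][c]] > level) ins[ni++] = tet[t][c];
            else outs[no++] = tet[t][c];
          }
          if (ni == 0 || ni == 4) continue;
          double v1[3], v2[3], v3[3], v4[3];
          if (ni == 1 || ni == 3) {
            int apex = (ni == 1) ? ins[0] : outs[0];
            int *oth = (ni == 1) ? outs : ins;
            interp(cp[apex], cp[oth[0]], cv[apex], cv[oth[0]], level, v1);
            interp(cp[apex], cp[oth[1]], cv[apex], cv[oth[1]], level, v2);
            interp(cp[apex], cp[oth[2]], cv[apex], cv[oth[2]], level, v3);
            total += tri_area(v1, v2, v3);
          } else {  // 2 in, 2 out: quad split into two triangles
            interp(cp[ins[0]], cp[outs[0]], cv[ins[0]], cv[outs[0]], level, v1);
            interp(cp[ins[0]], cp[outs[1]], cv[ins[0]], cv[outs[1]], level, v2);
            interp(cp[ins[1]], cp[outs[1]], cv[ins[1]], cv[outs[1]], level, v3);
            interp(cp[ins[1]], cp[outs[0]], cv[ins[1]], cv[outs[0]], level, v4);
            total += tri_area(v1, v3, v4) + tri_area(v1, v3, v2);
          }
        }
      }
  return total;
}
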