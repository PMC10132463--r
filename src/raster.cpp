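#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Rasterizers write object labels into an integer volume held by R
// (modified in place; callers own freshly allocated arrays). All
// geometric parameters are physical (nm); a voxel (i,j,k) has its
// centre at ((i+0.5)*sx + ox, (j+0.5)*sy + oy, (k+0.5)*sz + oz) where
// `origin` is the physical coordinate of the volume's corner.

static inline void bbox_range(double lo, double hi, double sp, double orig,
                              int n, int &i0, int &i1) {
  i0 = (int)std::floor((lo - orig) / sp - 0.5);
  i1 = (int)std::ceil((hi - orig) / sp - 0.5);
  if (i0 < 0) i0 = 0;
  if (i1 > n - 1) i1 = n - 1;
}

// [[Rcpp::export]]
int cpp_fill_ellipsoid(IntegerVector vol, IntegerVector dims, int label,
                       NumericVector center, NumericVector semiax,
                       NumericVector spacing, NumericVector origin) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  int x0, x1, y0, y1, z0, z1, cnt = 0;
  bbox_range(center[0] - semiax[0], center[0] + semiax[0], spacing[0],
             origin[0], nx, x0, x1);
  bbox_range(center[1] - semiax[1], center[1] + semiax[1], spacing[1],
             origin[1], ny, y0, y1);
  bbox_range(center[2] - semiax[2], center[2] + semiax[2], spacing[2],
             origin[2], nz, z0, z1);
  for (int z = z0; z <= z1; ++z) {
    double pz = (z + 0.5) * spacing[2] + origin[2];
    double fz = (pz - center[2]) / semiax[2];
    for (int y = y0; y <= y1; ++y) {
      double py = (y + 0.5) * spacing[1] + origin[1];
      double fy = (py - center[1]) / semiax[1];
      for (int x = x0; x <= x1; ++x) {
        double px = (x + 0.5) * spacing[0] + origin[0];
        double fx = (px - center[0]) / semiax[0];
        if (fx * fx + fy * fy + fz * fz <= 1.0) {
          vol[(R_xlen_t)x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)] = label;
          ++cnt;
        }
      }
    }
  }
  return cnt;
}

// Capsule: all points within `radius` of segment p1-p2.
// [[Rcpp::export]]
int cpp_fill_capsule(IntegerVector vol, IntegerVector dims, int label,
                     NumericVector p1, NumericVector p2, double radius,
                     NumericVector spacing, NumericVector origin) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) {
    lo[d] = std::min(p1[d], p2[d]) - radius;
    hi[d] = std::max(p1[d], p2[d]) + radius;
  }
  int x0, x1, y0, y1, z0, z1, cnt = 0;
  bbox_range(lo[0], hi[0], spacing[0], origin[0], nx, x0, x1);
  bbox_range(lo[1], hi[1], spacing[1], origin[1], ny, y0, y1);
  bbox_range(lo[2], hi[2], spacing[2], origin[2], nz, z0, z1);
  double ax = p2[0] - p1[0], ay = p2[1] - p1[1], az = p2[2] - p1[2];
  double aa = ax * ax + ay * ay + az * az;
  const double r2 = radius * radius;
  for (int z = z0; z <= z1; ++z) {
    double pz = (z + 0.5) * spacing[2] + origin[2];
    for (int y = y0; y <= y1; ++y) {
      double py = (y + 0.5) * spacing[1] + origin[1];
      for (int x = x0; x <= x1; ++x) {
        double px = (x + 0.5) * spacing[0] + origin[0];
        double wx = px - p1[0], wy = py - p1[1], wz = pz - p1[2];
        double t = aa > 0 ? (wx * ax + wy * ay + wz * az) / aa : 0.0;
        if (t < 0) t = 0; if (t > 1) t = 1;
        double dx = wx - t * ax, dy = wy - t * ay, dz = wz - t * az;
        if (dx * dx + dy * dy + dz * dz <= r2) {
          vol[(R_xlen_t)x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)] = label;
          ++cnt;
        }
      }
    }
  }
  return cnt;
}

// Solid torus with tube radius r around a circle of radius R centred at
// `center` in the plane orthogonal to the z axis (the generator keeps
// torus planes parallel to the sections so the through-hole survives
// section-thickness anisotropy).
// [[Rcpp::export]]
int cpp_fill_torus(IntegerVector vol, IntegerVector dims, int label,
                   NumericVector center, double R, double r,
                   NumericVector spacing, NumericVector origin) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  int x0, x1, y0, y1, z0, z1, cnt = 0;
  bbox_range(center[0] - R - r, center[0] + R + r, spacing[0], origin[0], nx,
             x0, x1);
  bbox_range(center[1] - R - r, center[1] + R + r, spacing[1], origin[1], ny,
             y0, y1);
  bbox_range(center[2] - r, center[2] + r, spacing[2], origin[2], nz, z0, z1);
  const double r2 = r * r;
  for (int z = z0; z <= z1; ++z) {
    double pz = (z + 0.5) * spacing[2] + origin[2] - center[2];
    for (int y = y0; y <= y1; ++y) {
      double py = (y + 0.5) * spacing[1] + origin[1] - center[1];
      for (int x = x0; x <= x1; ++x) {
        double px = (x + 0.5) * spacing[0] + origin[0] - center[0];
        double rho = std::sqrt(px * px + py * py) - R;
        if (rho * rho + pz * pz <= r2) {
          vol[(R_xlen_t)x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)] = label;
          ++cnt;
        }
      }
    }
  }
  return cnt;
}

// In-place sparse voxel writes (used by the synapse-ribbon painter so
// full-volume painting never copies the array at R level).
// [[Rcpp::export]]
void cpp_set_voxels(IntegerVector vol, NumericVector lin, int label) {
  for (R_xlen_t i = 0; i < lin.size(); ++i)
    vol[(R_xlen_t)lin[i] - 1] = label;
}

// Per-label bounding boxes of a label volume: returns a (maxLabel x 7)
// matrix [label, x0, x1, y0, y1, z0, z1] (1-based, 0 rows for absent
// labels filtered by the caller).
// [[Rcpp::export]]
IntegerMatrix cpp_label_bboxes(IntegerVector vol, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  int maxlab = 0;
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  for (R_xlen_t i = 0; i < n; ++i) if (vol[i] > maxlab) maxlab = vol[i];
  IntegerMatrix out(maxlab, 7);
  for (int l = 0; l < maxlab; ++l) {
    out(l, 0) = l + 1;
    out(l, 1) = nx + 1; out(l, 3) = ny + 1; out(l, 5) = nz + 1;
    out(l, 2) = 0; out(l, 4) = 0; out(l, 6) = 0;
  }
  R_xlen_t i = 0;
  for (int z = 1; z <= nz; ++z)
    for (int y = 1; y <= ny; ++y)
      for (int x = 1; x <= nx; ++x, ++i) {
        int l = vol[i] - 1;
        if (l < 0) continue;
        if (x < out(l, 1)) out(l, 1) = x;
        if (x > out(l, 2)) out(l, 2) = x;
        if (y < out(l, 3)) out(l, 3) = y;
        if (y > out(l, 4)) out(l, 4) = y;
        if (z < out(l, 5)) out(l, 5) = z;
        if (z > out(l, 6)) out(l, 6) = z;
      }
  return out;
}
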