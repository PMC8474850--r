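#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Trilinearly interpolated occupancy, thresholded at 0.5; points outside
// the grid count as empty. Compared with nearest-voxel lookup this places
// the effective bone surface within ~a quarter voxel of the true surface
// independent of orientation, instead of eroding by up to half a voxel
// diagonal. Grid is column-major (i fastest), origin at the centre of
// voxel (0,0,0).
static inline bool occ_at(const int *occ, const int *dim,
                          const double *origin, const double *spacing,
                          double x, double y, double z) {
  const double fi = (x - origin[0]) / spacing[0];
  const double fj = (y - origin[1]) / spacing[1];
  const double fk = (z - origin[2]) / spacing[2];
  const long i0 = (long)std::floor(fi);
  const long j0 = (long)std::floor(fj);
  const long k0 = (long)std::floor(fk);
  const double wi = fi - i0, wj = fj - j0, wk = fk - k0;
  double acc = 0.0;
  for (int di = 0; di < 2; ++di) {
    const long i = i0 + di;
    if (i < 0 || i >= dim[0]) continue;
    const double wx = di ? wi : 1.0 - wi;
    for (int dj = 0; dj < 2; ++dj) {
      const long j = j0 + dj;
      if (j < 0 || j >= dim[1]) continue;
      const double wy = dj ? wj : 1.0 - wj;
      for (int dk = 0; dk < 2; ++dk) {
        const long k = k0 + dk;
        if (k < 0 || k >= dim[2]) continue;
        const double wz = dk ? wk : 1.0 - wk;
        if (occ[i + (long)dim[0] * (j + (long)dim[1] * k)])
          acc += wx * wy * wz;
      }
    }
  }
  return acc >= 0.5;
}

// March a bundle of parallel rays through the occupancy grid.
// starts: n x 3 matrix of ray base points (depth 0); dir: unit direction.
// Depth samples run from tmin to tmax in increments of step.
// A ray is "safe" iff its bone intersection is one contiguous run
// (largest internal gap <= gap_tol, in mm) of length >= min_len.
// Returns n x 4: safe(0/1), entry depth, exit depth, max internal gap.
// [[Rcpp::export]]
NumericMatrix ray_profiles_cpp(IntegerVector occ, IntegerVector dim,
                               NumericVector origin, NumericVector spacing,
                               NumericMatrix starts, NumericVector dir,
                               double tmin, double tmax, double step,
                               double min_len, double gap_tol) {
  const int n = starts.nrow();
  const int nsteps = (int)std::floor((tmax - tmin) / step) + 1;
  NumericMatrix out(n, 4);
  const int *d = INTEGER(dim);
  const int *oc = INTEGER(occ);
  const double *org = REAL(origin), *sp = REAL(spacing);
  const double dx = dir[0], dy = dir[1], dz = dir[2];
  for (int r = 0; r < n; ++r) {
    const double x0 = starts(r, 0), y0 = starts(r, 1), z0 = starts(r, 2);
    double entry = NA_REAL, exit = NA_REAL, last_bone = NA_REAL, max_gap = 0.0;
    bool seen = false;
    for (int s = 0; s < nsteps; ++s) {
      const double t = tmin + s * step;
      if (occ_at(oc, d, org, sp, x0 + t * dx, y0 + t * dy, z0 + t * dz)) {
        if (!seen) { entry = t; seen = true; }
        else {
          const double gap = t - last_bone - step;
          if (gap > max_gap + 1e-9) max_gap = gap;
        }
        last_bone = t; exit = t;
      }
    }
    const bool safe = seen && (exit - entry >= min_len) &&
                      (max_gap <= gap_tol + 1e-9);
    out(r, 0) = safe ? 1.0 : 0.0;
    out(r, 1) = entry;
    out(r, 2) = exit;
    out(r, 3) = seen ? max_gap : NA_REAL;
  }
  return out;
}

// Exhaustively sample a finite cylinder (axis through `center`, orthonormal
// in-plane basis u,v) and test whether every sample lies in bone.
// Axial positions run t0..t1 (depths along the axis relative to `center`),
// radial rings at pitch `radial_step` up to radius (the boundary ring is
// always included), angular pitch chosen so arc length <= radial_step.
// [[Rcpp::export]]
LogicalVector cylinder_ok_cpp(IntegerVector occ, IntegerVector dim,
                              NumericVector origin, NumericVector spacing,
                              NumericVector center, NumericVector axis,
                              NumericVector u, NumericVector v,
                              double radius, double t0, double t1,
                              double axial_step, double radial_step) {
  const int *d = INTEGER(dim);
  const int *oc = INTEGER(occ);
  const double *org = REAL(origin), *sp = REAL(spacing);
  std::vector<double> radii;
  radii.push_back(0.0);
  for (double r = radial_step; r < radius - 1e-9; r += radial_step)
    radii.push_back(r);
  if (radius > 1e-9) radii.push_back(radius);
  const int nt = (int)std::floor((t1 - t0) / axial_step) + 1;
  for (int s = 0; s < nt; ++s) {
    const double t = t0 + s * axial_step;
    const double cx = center[0] + t * axis[0];
    const double cy = center[1] + t * axis[1];
    const double cz = center[2] + t * axis[2];
    for (size_t ri = 0; ri < radii.size(); ++ri) {
      const double r = radii[ri];
      int nang = r > 1e-9 ? std::max(8, (int)std::ceil(2.0 * M_PI * r / radial_step)) : 1;
      for (int a = 0; a < nang; ++a) {
        const double th = 2.0 * M_PI * a / nang;
        const double pu = r * std::cos(th), pv = r * std::sin(th);
        if (!occ_at(oc, d, org, sp,
                    cx + pu * u[0] + pv * v[0],
                    cy + pu * u[1] + pv * v[1],
                    cz + pu * u[2] + pv * v[2]))
          return LogicalVector::create(false);
      }
    }
  }
  return LogicalVector::create(true);
}

// Watertight-mesh voxelization by z-column ray parity.
// vertices: nv x 3 (mm), faces: nf x 3 (0-based). A voxel centre is inside
// iff an upward ray from it crosses the surface an odd number of times.
// Ray x/y positions are jittered by a tiny fixed offset to dodge edge hits.
// [[Rcpp::export]]
LogicalVector voxelize_mesh_cpp(NumericMatrix vertices, IntegerMatrix faces,
                                IntegerVector dim, NumericVector origin,
                                NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int nf = faces.nrow();
  LogicalVector out((long)nx * ny * nz);
  const double eps = 1e-7;
  for (int j = 0; j < ny; ++j) {
    const double y = origin[1] + j * spacing[1] + eps;
    for (int i = 0; i < nx; ++i) {
      const double x = origin[0] + i * spacing[0] + eps;
      std::vector<double> zs;
      for (int f = 0; f < nf; ++f) {
        const int a = faces(f, 0), b = faces(f, 1), c = faces(f, 2);
        const double ax = vertices(a, 0), ay = vertices(a, 1), az = vertices(a, 2);
        const double bx = vertices(b, 0), by = vertices(b, 1), bz = vertices(b, 2);
        const double cx = vertices(c, 0), cy = vertices(c, 1), cz = vertices(c, 2);
        // 2D barycentric test in the xy plane
        const double det = (by - ay) * (cx - ax) - (bx - ax) * (cy - ay);
        if (std::fabs(det) < 1e-14) continue; // vertical triangle: no area in xy
        const double l1 = ((by - ay) * (x - ax) - (bx - ax) * (y - ay)) / det;  // weight of C
        const double l2 = -((cy - ay) * (x - ax) - (cx - ax) * (y - ay)) / det; // weight of B
        const double l0 = 1.0 - l1 - l2;
        if (l0 < 0 || l1 < 0 || l2 < 0) continue;
        zs.push_back(l0 * az + l2 * bz + l1 * cz);
      }
      if (zs.empty()) continue;
      std::sort(zs.begin(), zs.end());
      for (int k = 0; k < nz; ++k) {
        const double z = origin[2] + k * spacing[2];
        // count crossings strictly above z
        const int above = (int)(zs.end() - std::upper_bound(zs.begin(), zs.end(), z));
        if (above % 2 == 1)
          out[i + (long)nx * (j + (long)ny * k)] = true;
      }
    }
  }
  return out;
}
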