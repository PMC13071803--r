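#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Guarded trilinear sample at continuous 0-based index: corners outside
// the grid contribute 0, so the volume fades to zero across a one-voxel
// fringe instead of cutting off abruptly.
static inline double trilinear_border(const double* vol, const int* d,
                                      double x, double y, double z) {
  if (x < -1 || y < -1 || z < -1 ||
      x > d[0] || y > d[1] || z > d[2]) return 0.0;
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y),
      k0 = (int)std::floor(z);
  double fx = x - i0, fy = y - j0, fz = z - k0;
  double acc = 0.0;
  for (int dk = 0; dk <= 1; ++dk) {
    int k = k0 + dk;
    if (k < 0 || k >= d[2]) continue;
    double wk = dk ? fz : 1.0 - fz;
    for (int dj = 0; dj <= 1; ++dj) {
      int j = j0 + dj;
      if (j < 0 || j >= d[1]) continue;
      double wkj = wk * (dj ? fy : 1.0 - fy);
      const double* col = vol + ((size_t)k * d[1] + j) * d[0];
      for (int di = 0; di <= 1; ++di) {
        int i = i0 + di;
        if (i < 0 || i >= d[0]) continue;
        acc += wkj * (di ? fx : 1.0 - fx) * col[i];
      }
    }
  }
  return acc;
}

// Line-integral DRR: for each pixel in the ROI, march along the ray
// from the source through the pixel centre, sampling the posed volume
// by trilinear interpolation every <= step mm inside the world-space
// bounding box [lo, hi]; pixel value = sum(samples) * dt.
// B and c0 encode the world -> continuous-voxel-index affine map
// (index_i = (B p + c0)_i / spacing_i).
// [[Rcpp::export]]
NumericMatrix drr_render_cpp(NumericVector vol, IntegerVector dim,
                             NumericVector spacing,
                             NumericMatrix B, NumericVector c0,
                             NumericVector source, NumericMatrix rayM,
                             int nrow, int ncol, IntegerVector roi,
                             NumericVector lo, NumericVector hi,
                             double step) {
  if (step <= 0) stop("step must be positive");
  NumericMatrix out(nrow, ncol);
  const double* v = vol.begin();
  int d[3] = {dim[0], dim[1], dim[2]};
  const int nx = d[0], nxy = d[0] * d[1];
  double b11 = B(0,0) / spacing[0], b12 = B(0,1) / spacing[0],
         b13 = B(0,2) / spacing[0];
  double b21 = B(1,0) / spacing[1], b22 = B(1,1) / spacing[1],
         b23 = B(1,2) / spacing[1];
  double b31 = B(2,0) / spacing[2], b32 = B(2,1) / spacing[2],
         b33 = B(2,2) / spacing[2];
  double e0 = c0[0] / spacing[0], e1 = c0[1] / spacing[1],
         e2 = c0[2] / spacing[2];
  double m11 = rayM(0,0), m12 = rayM(0,1), m13 = rayM(0,2);
  double m21 = rayM(1,0), m22 = rayM(1,1), m23 = rayM(1,2);
  double m31 = rayM(2,0), m32 = rayM(2,1), m33 = rayM(2,2);
  double sx = source[0], sy = source[1], sz = source[2];
  // source position in index space
  double six = b11 * sx + b12 * sy + b13 * sz + e0;
  double siy = b21 * sx + b22 * sy + b23 * sz + e1;
  double siz = b31 * sx + b32 * sy + b33 * sz + e2;

  for (int r = roi[0]; r <= roi[1]; ++r) {
    for (int c = roi[2]; c <= roi[3]; ++c) {
      double u = (double)c, w = (double)r;
      double dx = m11 * u + m12 * w + m13;
      double dy = m21 * u + m22 * w + m23;
      double dz = m31 * u + m32 * w + m33;
      double n = std::sqrt(dx * dx + dy * dy + dz * dz);
      dx /= n; dy /= n; dz /= n;

      // slab clipping against the world AABB
      double t0 = 0.0, t1 = R_PosInf;
      bool miss = false;
      double so[3] = {sx, sy, sz}, dd[3] = {dx, dy, dz};
      for (int a = 0; a < 3 && !miss; ++a) {
        if (std::fabs(dd[a]) < 1e-12) {
          if (so[a] < lo[a] || so[a] > hi[a]) miss = true;
        } else {
          double ta = (lo[a] - so[a]) / dd[a];
          double tb = (hi[a] - so[a]) / dd[a];
          if (ta > tb) std::swap(ta, tb);
          if (ta > t0) t0 = ta;
          if (tb < t1) t1 = tb;
          if (t0 > t1) miss = true;
        }
      }
      if (miss || t1 <= t0) continue;

      int nsteps = (int)std::ceil((t1 - t0) / step);
      if (nsteps < 1) nsteps = 1;
      double dt = (t1 - t0) / nsteps;
      // ray direction in index space, per dt
      double gx = (b11 * dx + b12 * dy + b13 * dz) * dt;
      double gy = (b21 * dx + b22 * dy + b23 * dz) * dt;
      double gz = (b31 * dx + b32 * dy + b33 * dz) * dt;
      double t00 = t0 + 0.5 * dt;
      double ix = six + (t00 / dt) * gx;
      double iy = siy + (t00 / dt) * gy;
      double iz = siz + (t00 / dt) * gz;
      double acc = 0.0;
      for (int k = 0; k < nsteps; ++k) {
        if (ix >= 0 && iy >= 0 && iz >= 0 &&
            ix < d[0] - 1 && iy < d[1] - 1 && iz < d[2] - 1) {
          int i0 = (int)ix, j0 = (int)iy, k0 = (int)iz;
          double fx = ix - i0, fy = iy - j0, fz = iz - k0;
          const double* p = v + (size_t)k0 * nxy + (size_t)j0 * nx + i0;
          double c00 = p[0] + fx * (p[1] - p[0]);
          double c10 = p[nx] + fx * (p[nx + 1] - p[nx]);
          double c01 = p[nxy] + fx * (p[nxy + 1] - p[nxy]);
          double c11 = p[nxy + nx] + fx * (p[nxy + nx + 1] - p[nxy + nx]);
          double c0v = c00 + fy * (c10 - c00);
          double c1v = c01 + fy * (c11 - c01);
          acc += c0v + fz * (c1v - c0v);
        } else {
          acc += trilinear_border(v, d, ix, iy, iz);
        }
        ix += gx; iy += gy; iz += gz;
      }
      out(r, c) = acc * dt;
    }
  }
  return out;
}
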