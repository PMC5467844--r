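#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Fan-beam geometry convention (shared with the R side):
//   - world coordinates in mm, image centre at the isocenter, x right, y up;
//   - image matrix: first index = x, second index = y, pixel centres at
//     ((i - (n-1)/2) * pitch, (j - (n-1)/2) * pitch), 0-based i, j;
//   - at view angle beta the source sits at sid * (cos b, sin b); the flat
//     detector centre sits at -(sdd - sid) * (cos b, sin b) and the channel
//     axis points along e_u = (-sin b, cos b); channel c (0-based) is at
//     signed offset u = (c - (n_ch - 1)/2) * ch_pitch along e_u.

// Clip the ray s + t * d, t in [0, len], against the square [-half, half]^2.
// Returns false when the ray misses the square.
static bool clip_to_square(double sx, double sy, double dx, double dy,
                           double len, double half, double &t0, double &t1) {
  t0 = 0.0;
  t1 = len;
  const double eps = 1e-12;
  // x slab
  if (std::fabs(dx) < eps) {
    if (sx < -half || sx > half) return false;
  } else {
    double ta = (-half - sx) / dx, tb = (half - sx) / dx;
    if (ta > tb) std::swap(ta, tb);
    if (ta > t0) t0 = ta;
    if (tb < t1) t1 = tb;
  }
  // y slab
  if (std::fabs(dy) < eps) {
    if (sy < -half || sy > half) return false;
  } else {
    double ta = (-half - sy) / dy, tb = (half - sy) / dy;
    if (ta > tb) std::swap(ta, tb);
    if (ta > t0) t0 = ta;
    if (tb < t1) t1 = tb;
  }
  return t1 > t0;
}

// Joseph-style ray-driven fan-beam forward projection: line integrals of a
// bilinearly interpolated image, sampled at step_frac * pitch along each ray.
// [[Rcpp::export]]
NumericMatrix cpp_fan_forward(NumericMatrix img, double pitch,
                              double sid, double sdd,
                              int n_ch, double ch_pitch,
                              NumericVector angles, double step_frac) {
  const int n = img.nrow();
  if (img.ncol() != n) stop("image must be square");
  const int nv = angles.size();
  NumericMatrix out(nv, n_ch);
  const double half = 0.5 * n * pitch;
  const double c0 = 0.5 * (n - 1);
  const double uc = 0.5 * (n_ch - 1);

  for (int v = 0; v < nv; ++v) {
    const double b = angles[v];
    const double cb = std::cos(b), sb = std::sin(b);
    const double sx = sid * cb, sy = sid * sb;
    const double dcx = -(sdd - sid) * cb, dcy = -(sdd - sid) * sb;
    for (int c = 0; c < n_ch; ++c) {
      const double u = (c - uc) * ch_pitch;
      double dx = dcx - u * sb - sx, dy = dcy + u * cb - sy;
      const double len = std::sqrt(dx * dx + dy * dy);
      dx /= len;
      dy /= len;
      double t0, t1;
      if (!clip_to_square(sx, sy, dx, dy, len, half, t0, t1)) continue;
      const int ns = (int)std::ceil((t1 - t0) / (pitch * step_frac));
      if (ns <= 0) continue;
      const double ds = (t1 - t0) / ns;
      double acc = 0.0;
      for (int k = 0; k < ns; ++k) {
        const double t = t0 + (k + 0.5) * ds;
        const double gx = (sx + t * dx) / pitch + c0;
        const double gy = (sy + t * dy) / pitch + c0;
        const int ix = (int)std::floor(gx), iy = (int)std::floor(gy);
        if (ix < 0 || ix >= n - 1 || iy < 0 || iy >= n - 1) continue;
        const double fx = gx - ix, fy = gy - iy;
        acc += img(ix, iy) * (1 - fx) * (1 - fy) + img(ix + 1, iy) * fx * (1 - fy) +
               img(ix, iy + 1) * (1 - fx) * fy + img(ix + 1, iy + 1) * fx * fy;
      }
      out(v, c) = acc * ds;
    }
  }
  return out;
}

// Exact transpose of cpp_fan_forward: spreads sinogram values back along the
// same sampled rays with the same bilinear weights (unfiltered backprojection;
// used for adjoint checks, not for FBP).
// [[Rcpp::export]]
NumericMatrix cpp_fan_adjoint(NumericMatrix sino, int n, double pitch,
                              double sid, double sdd,
                              int n_ch, double ch_pitch,
                              NumericVector angles, double step_frac) {
  const int nv = angles.size();
  if (sino.nrow() != nv || sino.ncol() != n_ch) stop("sinogram shape mismatch");
  NumericMatrix img(n, n);
  const double half = 0.5 * n * pitch;
  const double c0 = 0.5 * (n - 1);
  const double uc = 0.5 * (n_ch - 1);

  for (int v = 0; v < nv; ++v) {
    const double b = angles[v];
    const double cb = std::cos(b), sb = std::sin(b);
    const double sx = sid * cb, sy = sid * sb;
    const double dcx = -(sdd - sid) * cb, dcy = -(sdd - sid) * sb;
    for (int c = 0; c < n_ch; ++c) {
      const double g = sino(v, c);
      if (g == 0.0) continue;
      const double u = (c - uc) * ch_pitch;
      double dx = dcx - u * sb - sx, dy = dcy + u * cb - sy;
      const double len = std::sqrt(dx * dx + dy * dy);
      dx /= len;
      dy /= len;
      double t0, t1;
      if (!clip_to_square(sx, sy, dx, dy, len, half, t0, t1)) continue;
      const int ns = (int)std::ceil((t1 - t0) / (pitch * step_frac));
      if (ns <= 0) continue;
      const double ds = (t1 - t0) / ns;
      const double w = g * ds;
      for (int k = 0; k < ns; ++k) {
        const double t = t0 + (k + 0.5) * ds;
        const double gx = (sx + t * dx) / pitch + c0;
        const double gy = (sy + t * dy) / pitch + c0;
        const int ix = (int)std::floor(gx), iy = (int)std::floor(gy);
        if (ix < 0 || ix >= n - 1 || iy < 0 || iy >= n - 1) continue;
        const double fx = gx - ix, fy = gy - iy;
        img(ix, iy) += w * (1 - fx) * (1 - fy);
        img(ix + 1, iy) += w * fx * (1 - fy);
        img(ix, iy + 1) += w * (1 - fx) * fy;
        img(ix + 1, iy + 1) += w * fx * fy;
      }
    }
  }
  return img;
}

// Pixel-driven distance-weighted fan-beam backprojection of ramp-filtered
// projections resampled on the virtual detector through the isocenter
// (channel spacing du_iso). Applies the 1/U^2 magnification weight; the
// caller supplies cosine-weighted, filtered data and the d_beta scale.
// [[Rcpp::export]]
NumericMatrix cpp_fan_backproject(NumericMatrix q, double sid,
                                  int n, double pitch, double du_iso,
                                  NumericVector angles) {
  const int nv = q.nrow(), nch = q.ncol();
  if (angles.size() != nv) stop("angles/projection count mismatch");
  NumericMatrix img(n, n);
  const double c0 = 0.5 * (n - 1);
  const double cch = 0.5 * (nch - 1);

  for (int v = 0; v < nv; ++v) {
    const double b = angles[v];
    const double cb = std::cos(b), sb = std::sin(b);
    for (int iy = 0; iy < n; ++iy) {
      const double y = (iy - c0) * pitch;
      for (int ix = 0; ix < n; ++ix) {
        const double x = (ix - c0) * pitch;
        const double sr = x * cb + y * sb;       // toward the source
        const double t = -x * sb + y * cb;       // along the channel axis
        const double U = (sid - sr) / sid;
        if (U <= 1e-6) continue;
        const double ci = (t / U) / du_iso + cch;
        const int i0 = (int)std::floor(ci);
        if (i0 < 0 || i0 >= nch - 1) continue;
        const double f = ci - i0;
        img(ix, iy) += (q(v, i0) * (1 - f) + q(v, i0 + 1) * f) / (U * U);
      }
    }
  }
  const double dbeta = 2.0 * M_PI / nv;
  for (int i = 0; i < n * n; ++i) img[i] *= dbeta;
  return img;
}
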