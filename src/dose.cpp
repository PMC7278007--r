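#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Amanatides-Woo voxel traversal: exact line integral of a piecewise-
// constant (per-voxel) density along the segment src -> dst, in
// density * mm. Voxel (i,j,k) spans world
// [origin + (i-0.5)*sp, origin + (i+0.5)*sp) per axis.
static double ray_integral(const NumericVector& dens, int nx, int ny, int nz,
                           const double* sp, const double* org,
                           const double* src, const double* dst) {
  double dir[3], box0[3], box1[3];
  int dim[3] = {nx, ny, nz};
  double len = 0;
  for (int a = 0; a < 3; ++a) {
    dir[a] = dst[a] - src[a];
    len += dir[a] * dir[a];
    box0[a] = org[a] - 0.5 * sp[a];
    box1[a] = org[a] + (dim[a] - 0.5) * sp[a];
  }
  len = std::sqrt(len);
  if (len <= 0) return 0.0;
  // clip segment to the volume box (slab method), t in [0,1]
  double t0 = 0.0, t1 = 1.0;
  for (int a = 0; a < 3; ++a) {
    if (std::fabs(dir[a]) < 1e-12) {
      if (src[a] < box0[a] || src[a] > box1[a]) return 0.0;
    } else {
      double ta = (box0[a] - src[a]) / dir[a];
      double tb = (box1[a] - src[a]) / dir[a];
      if (ta > tb) std::swap(ta, tb);
      t0 = std::max(t0, ta);
      t1 = std::min(t1, tb);
    }
  }
  if (t1 <= t0) return 0.0;
  // entry voxel
  double p[3];
  int iv[3];
  for (int a = 0; a < 3; ++a) {
    p[a] = src[a] + t0 * dir[a];
    double ci = (p[a] - org[a]) / sp[a];
    iv[a] = (int)std::floor(ci + 0.5);
    if (iv[a] < 0) iv[a] = 0;
    if (iv[a] >= dim[a]) iv[a] = dim[a] - 1;
  }
  double tMax[3], tDelta[3];
  int step[3];
  for (int a = 0; a < 3; ++a) {
    if (std::fabs(dir[a]) < 1e-12) {
      step[a] = 0;
      tMax[a] = INFINITY;
      tDelta[a] = INFINITY;
    } else {
      step[a] = dir[a] > 0 ? 1 : -1;
      double boundary = org[a] + (iv[a] + (step[a] > 0 ? 0.5 : -0.5)) * sp[a];
      tMax[a] = (boundary - src[a]) / dir[a];
      tDelta[a] = sp[a] / std::fabs(dir[a]);
    }
  }
  double integral = 0.0, t = t0;
  while (t < t1) {
    int a = 0;
    if (tMax[1] < tMax[a]) a = 1;
    if (tMax[2] < tMax[a]) a = 2;
    double tNext = std::min(tMax[a], t1);
    double seg = (tNext - t) * len;
    if (seg > 0) {
      integral += seg * dens[(size_t)iv[0] + nx * ((size_t)iv[1] + (size_t)ny * iv[2])];
    }
    t = tNext;
    if (tMax[a] <= t1) {
      iv[a] += step[a];
      if (iv[a] < 0 || iv[a] >= dim[a]) break;
      tMax[a] += tDelta[a];
    }
  }
  return integral;
}

// [[Rcpp::export(name = ".ray_integral_cpp")]]
double ray_integral_cpp(NumericVector dens, IntegerVector dim,
                        NumericVector spacing, NumericVector origin,
                        NumericVector src, NumericVector dst) {
  double sp[3] = {spacing[0], spacing[1], spacing[2]};
  double org[3] = {origin[0], origin[1], origin[2]};
  double s[3] = {src[0], src[1], src[2]};
  double d[3] = {dst[0], dst[1], dst[2]};
  return ray_integral(dens, dim[0], dim[1], dim[2], sp, org, s, d);
}

// Divergent exponential-attenuation pencil model with error-function
// lateral penumbra. beams: one row per beam with columns
// (src_x, src_y, src_z, iso_x, iso_y, iso_z, sad, field, weight).
// Returns unnormalised dose (D0 = 1), zero outside `body`.
// [[Rcpp::export(name = ".compute_dose_cpp")]]
NumericVector compute_dose_cpp(NumericVector dens, IntegerVector dim,
                               NumericVector spacing, NumericVector origin,
                               LogicalVector body, NumericMatrix beams,
                               double mu, double sigma) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  double sp[3] = {spacing[0], spacing[1], spacing[2]};
  double org[3] = {origin[0], origin[1], origin[2]};
  size_t n = (size_t)nx * ny * nz;
  NumericVector dose(n, 0.0);
  const double SQRT2 = std::sqrt(2.0);
  for (int b = 0; b < beams.nrow(); ++b) {
    double src[3] = {beams(b, 0), beams(b, 1), beams(b, 2)};
    double iso[3] = {beams(b, 3), beams(b, 4), beams(b, 5)};
    double sad = beams(b, 6), field = beams(b, 7), w = beams(b, 8);
    double ax[3];
    double norm = 0;
    for (int a = 0; a < 3; ++a) {
      ax[a] = iso[a] - src[a];
      norm += ax[a] * ax[a];
    }
    norm = std::sqrt(norm);
    for (int a = 0; a < 3; ++a) ax[a] /= norm;
    // lateral basis
    double e[3] = {0, 0, 1};
    if (std::fabs(ax[2]) > 0.9) { e[0] = 1; e[2] = 0; }
    double u1[3] = {ax[1] * e[2] - ax[2] * e[1],
                    ax[2] * e[0] - ax[0] * e[2],
                    ax[0] * e[1] - ax[1] * e[0]};
    double nu = std::sqrt(u1[0] * u1[0] + u1[1] * u1[1] + u1[2] * u1[2]);
    for (int a = 0; a < 3; ++a) u1[a] /= nu;
    double u2[3] = {ax[1] * u1[2] - ax[2] * u1[1],
                    ax[2] * u1[0] - ax[0] * u1[2],
                    ax[0] * u1[1] - ax[1] * u1[0]};
    double half = field / 2.0;
    size_t idx = 0;
    for (int k = 0; k < nz; ++k) {
      double wz = org[2] + k * sp[2];
      for (int j = 0; j < ny; ++j) {
        double wy = org[1] + j * sp[1];
        for (int i = 0; i < nx; ++i, ++idx) {
          if (!body[idx]) continue;
          double wx = org[0] + i * sp[0];
          double d[3] = {wx - src[0], wy - src[1], wz - src[2]};
          double t = d[0] * ax[0] + d[1] * ax[1] + d[2] * ax[2];
          if (t <= 1.0) continue;
          double lu = d[0] * u1[0] + d[1] * u1[1] + d[2] * u1[2];
          double lv = d[0] * u2[0] + d[1] * u2[1] + d[2] * u2[2];
          double scale = sad / t;  // project to isocentre plane
          double su = lu * scale, sv = lv * scale;
          if (std::fabs(su) > half + 5 * sigma || std::fabs(sv) > half + 5 * sigma)
            continue;
          double pu = 0.5 * (std::erf((half - su) / (SQRT2 * sigma)) +
                             std::erf((half + su) / (SQRT2 * sigma)));
          double pv = 0.5 * (std::erf((half - sv) / (SQRT2 * sigma)) +
                             std::erf((half + sv) / (SQRT2 * sigma)));
          double pen = pu * pv;
          if (pen < 1e-7) continue;
          double vox[3] = {wx, wy, wz};
          double drad = ray_integral(dens, nx, ny, nz, sp, org, src, vox);
          double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
          dose[idx] += w * std::exp(-mu * drad) * (sad * sad / r2) * pen;
        }
      }
    }
  }
  return dose;
}
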