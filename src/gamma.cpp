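#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Global 3D gamma index. Reference and evaluated doses share one grid.
// For each reference voxel above the low-dose threshold the evaluated
// dose is probed, via trilinear interpolation, on an offset lattice of
// step `step` mm out to radius cap*dta; offsets are visited in order of
// increasing distance so the search can stop as soon as the pure
// distance term exceeds the best gamma found (exact pruning).
// [[Rcpp::export(name = ".gamma_map_cpp")]]
NumericVector gamma_map_cpp(NumericVector ref, NumericVector eval,
                            IntegerVector dim, NumericVector spacing,
                            double dcrit, double dta, double thr,
                            double cap, double step) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  double radius = cap * dta;
  int m = (int)std::floor(radius / step);
  // offset lattice sorted by radius
  struct Off { double dx, dy, dz, r2n; };
  std::vector<Off> offs;
  offs.reserve((size_t)(2 * m + 1) * (2 * m + 1) * (2 * m + 1) / 2);
  for (int a = -m; a <= m; ++a)
    for (int b = -m; b <= m; ++b)
      for (int c = -m; c <= m; ++c) {
        double dx = a * step, dy = b * step, dz = c * step;
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 > radius * radius) continue;
        offs.push_back({dx, dy, dz, r2 / (dta * dta)});
      }
  std::sort(offs.begin(), offs.end(),
            [](const Off& p, const Off& q) { return p.r2n < q.r2n; });

  auto interp = [&](double cx, double cy, double cz, bool& ok) -> double {
    if (cx < 0 || cy < 0 || cz < 0 || cx > nx - 1 || cy > ny - 1 || cz > nz - 1) {
      ok = false;
      return 0.0;
    }
    ok = true;
    int x0 = std::min((int)std::floor(cx), nx - 2);
    int y0 = std::min((int)std::floor(cy), ny - 2);
    int z0 = std::min((int)std::floor(cz), nz - 2);
    if (x0 < 0) x0 = 0;
    if (y0 < 0) y0 = 0;
    if (z0 < 0) z0 = 0;
    double fx = cx - x0, fy = cy - y0, fz = cz - z0;
    auto at = [&](int i, int j, int k) {
      return eval[(size_t)i + nx * ((size_t)j + (size_t)ny * k)];
    };
    double c00 = at(x0, y0, z0) * (1 - fx) + at(x0 + 1, y0, z0) * fx;
    double c10 = at(x0, y0 + 1, z0) * (1 - fx) + at(x0 + 1, y0 + 1, z0) * fx;
    double c01 = at(x0, y0, z0 + 1) * (1 - fx) + at(x0 + 1, y0, z0 + 1) * fx;
    double c11 = at(x0, y0 + 1, z0 + 1) * (1 - fx) + at(x0 + 1, y0 + 1, z0 + 1) * fx;
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    return c0 * (1 - fz) + c1 * fz;
  };

  NumericVector out(n, NA_REAL);
  double cap2 = cap * cap;
  double dta2 = dta * dta;
  size_t idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx) {
        double Dr = ref[idx];
        if (!(Dr > thr)) continue;
        double best2 = cap2;
        double bx = 0, by = 0, bz = 0;
        for (const Off& o : offs) {
          if (o.r2n >= best2) break;
          bool ok;
          double De = interp(i + o.dx / spacing[0], j + o.dy / spacing[1],
                             k + o.dz / spacing[2], ok);
          if (!ok) continue;
          double dd = (De - Dr) / dcrit;
          double g2 = o.r2n + dd * dd;
          if (g2 < best2) {
            best2 = g2;
            bx = o.dx; by = o.dy; bz = o.dz;
          }
        }
        // compass-search refinement around the best lattice offset:
        // the gamma surface is piecewise smooth between lattice points
        double fstep = step / 2;
        while (fstep > 0.004) {
          bool moved = false;
          for (int a = 0; a < 6; ++a) {
            double cx = bx, cy = by, cz = bz;
            if (a == 0) cx += fstep;
            if (a == 1) cx -= fstep;
            if (a == 2) cy += fstep;
            if (a == 3) cy -= fstep;
            if (a == 4) cz += fstep;
            if (a == 5) cz -= fstep;
            double r2n = (cx * cx + cy * cy + cz * cz) / dta2;
            if (r2n >= best2) continue;
            bool ok;
            double De = interp(i + cx / spacing[0], j + cy / spacing[1],
                               k + cz / spacing[2], ok);
            if (!ok) continue;
            double dd = (De - Dr) / dcrit;
            double g2 = r2n + dd * dd;
            if (g2 < best2) {
              best2 = g2;
              bx = cx; by = cy; bz = cz;
              moved = true;
            }
          }
          if (!moved) fstep /= 2;
        }
        out[idx] = std::sqrt(best2);
        if (out[idx] > cap) out[idx] = cap;
      }
  return out;
}
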