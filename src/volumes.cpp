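#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Voxel-centered geometry: world(i) = origin + i*spacing (0-based, x fastest).

static inline double trilinear(const NumericVector& v,
                               int nx, int ny, int nz,
                               double cx, double cy, double cz,
                               bool& ok) {
  if (cx < 0 || cy < 0 || cz < 0 || cx > nx - 1 || cy > ny - 1 || cz > nz - 1) {
    ok = false;
    return 0.0;
  }
  ok = true;
  int x0 = (int)std::floor(cx), y0 = (int)std::floor(cy), z0 = (int)std::floor(cz);
  if (x0 == nx - 1) x0--;
  if (y0 == ny - 1) y0--;
  if (z0 == nz - 1) z0--;
  if (nx == 1) x0 = 0;
  if (ny == 1) y0 = 0;
  if (nz == 1) z0 = 0;
  double fx = cx - x0, fy = cy - y0, fz = cz - z0;
  if (nx == 1) fx = 0;
  if (ny == 1) fy = 0;
  if (nz == 1) fz = 0;
  int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1), z1 = std::min(z0 + 1, nz - 1);
  auto at = [&](int i, int j, int k) {
    return v[(size_t)i + nx * ((size_t)j + (size_t)ny * k)];
  };
  double c00 = at(x0, y0, z0) * (1 - fx) + at(x1, y0, z0) * fx;
  double c10 = at(x0, y1, z0) * (1 - fx) + at(x1, y1, z0) * fx;
  double c01 = at(x0, y0, z1) * (1 - fx) + at(x1, y0, z1) * fx;
  double c11 = at(x0, y1, z1) * (1 - fx) + at(x1, y1, z1) * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// [[Rcpp::export(name = ".resample_cpp")]]
NumericVector resample_cpp(NumericVector values, IntegerVector dim,
                           NumericVector spacing, NumericVector origin,
                           IntegerVector tdim, NumericVector tspacing,
                           NumericVector torigin, std::string mode,
                           double fill) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int tx = tdim[0], ty = tdim[1], tz = tdim[2];
  NumericVector out((size_t)tx * ty * tz);
  bool nearest = (mode == "nearest");
  size_t idx = 0;
  for (int k = 0; k < tz; ++k) {
    double wz = torigin[2] + k * tspacing[2];
    double cz = (wz - origin[2]) / spacing[2];
    for (int j = 0; j < ty; ++j) {
      double wy = torigin[1] + j * tspacing[1];
      double cy = (wy - origin[1]) / spacing[1];
      for (int i = 0; i < tx; ++i, ++idx) {
        double wx = torigin[0] + i * tspacing[0];
        double cx = (wx - origin[0]) / spacing[0];
        if (nearest) {
          int ix = (int)std::lround(cx), iy = (int)std::lround(cy), iz = (int)std::lround(cz);
          if (ix < 0 || iy < 0 || iz < 0 || ix >= nx || iy >= ny || iz >= nz) {
            out[idx] = fill;
          } else {
            out[idx] = values[(size_t)ix + nx * ((size_t)iy + (size_t)ny * iz)];
          }
        } else {
          bool ok;
          double val = trilinear(values, nx, ny, nz, cx, cy, cz, ok);
          out[idx] = ok ? val : fill;
        }
      }
    }
  }
  return out;
}

// Felzenszwalb & Huttenlocher 1D squared distance transform on a sampled
// line with physical step h; f holds squared distances, overwritten.
static void dt1d(std::vector<double>& f, double h) {
  int n = (int)f.size();
  if (n == 1) return;
  std::vector<int> v(n);
  std::vector<double> z(n + 1), d(n);
  int k = 0;
  v[0] = 0;
  z[0] = -INFINITY;
  z[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double qq = (double)q * h;
    double s;
    while (true) {
      double vp = (double)v[k] * h;
      s = ((f[q] + qq * qq) - (f[v[k]] + vp * vp)) / (2 * qq - 2 * vp);
      if (s <= z[k]) {
        k--;
      } else break;
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double qq = (double)q * h;
    while (z[k + 1] < qq) k++;
    double vp = (double)v[k] * h;
    d[q] = (qq - vp) * (qq - vp) + f[v[k]];
  }
  for (int q = 0; q < n; ++q) f[q] = d[q];
}

// [[Rcpp::export(name = ".distance_transform_cpp")]]
NumericVector distance_transform_cpp(LogicalVector mask, IntegerVector dim,
                                     NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  NumericVector out(n);
  const double INF = 1e30;
  for (size_t i = 0; i < n; ++i) out[i] = mask[i] ? 0.0 : INF;
  std::vector<double> line;
  // x pass
  line.resize(nx);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      size_t base = nx * ((size_t)j + (size_t)ny * k);
      for (int i = 0; i < nx; ++i) line[i] = out[base + i];
      dt1d(line, spacing[0]);
      for (int i = 0; i < nx; ++i) out[base + i] = line[i];
    }
  // y pass
  line.resize(ny);
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) line[j] = out[(size_t)i + nx * ((size_t)j + (size_t)ny * k)];
      dt1d(line, spacing[1]);
      for (int j = 0; j < ny; ++j) out[(size_t)i + nx * ((size_t)j + (size_t)ny * k)] = line[j];
    }
  // z pass
  line.resize(nz);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k) line[k] = out[(size_t)i + nx * ((size_t)j + (size_t)ny * k)];
      dt1d(line, spacing[2]);
      for (int k = 0; k < nz; ++k) out[(size_t)i + nx * ((size_t)j + (size_t)ny * k)] = std::sqrt(line[k]);
    }
  return out;
}

// 6-connected component labelling; returns 0 outside mask, 1..n inside.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  int cur = 0;
  std::queue<size_t> q;
  for (size_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    cur++;
    lab[s] = cur;
    q.push(s);
    while (!q.empty()) {
      size_t p = q.front();
      q.pop();
      int i = (int)(p % nx);
      int j = (int)((p / nx) % ny);
      int k = (int)(p / ((size_t)nx * ny));
      const int di[6] = {-1, 1, 0, 0, 0, 0};
      const int dj[6] = {0, 0, -1, 1, 0, 0};
      const int dk[6] = {0, 0, 0, 0, -1, 1};
      for (int t = 0; t < 6; ++t) {
        int ii = i + di[t], jj = j + dj[t], kk = k + dk[t];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
        size_t pp = (size_t)ii + nx * ((size_t)jj + (size_t)ny * kk);
        if (mask[pp] && lab[pp] == 0) {
          lab[pp] = cur;
          q.push(pp);
        }
      }
    }
  }
  return lab;
}
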