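// Low-level 3D voxel primitives. All volumes are column-major double/logical
// vectors with dim = c(nx, ny, nz); voxel centres sit at 0-based integer
// coordinates scaled by the per-axis spacing (micrometres).
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <cstdint>
#include <limits>
using namespace Rcpp;

static const double INF = 1e30;

// 1-D squared-distance transform (lower envelope of parabolas).
static void dt1d(const double* f, double* d, int n, double w2,
                 std::vector<int>& v, std::vector<double>& z) {
  const double NEGINF = -std::numeric_limits<double>::infinity();
  const double POSINF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0; z[0] = NEGINF; z[1] = POSINF;
  for (int q = 1; q < n; q++) {
    double s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
               (2.0 * w2 * (q - v[k]));
    while (s <= z[k]) {
      k--;
      s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
          (2.0 * w2 * (q - v[k]));
    }
    k++;
    v[k] = q; z[k] = s; z[k + 1] = POSINF;
  }
  k = 0;
  for (int x = 0; x < n; x++) {
    while (z[k + 1] < x) k++;
    double dx = (double)(x - v[k]);
    d[x] = w2 * dx * dx + f[v[k]];
  }
}

// Squared Euclidean distance (in micrometres^2) from every voxel to the
// nearest feature (TRUE) voxel. Anisotropic spacing supported.
// [[Rcpp::export(name = ".edt_sq")]]
NumericVector edt_sq(LogicalVector mask, IntegerVector dim,
                     NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = mask[i] ? 0.0 : INF;
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax);
  std::vector<int> v(nmax);
  std::vector<double> z(nmax + 1);
  // x pass
  double w2 = spacing[0] * spacing[0];
  for (int zz = 0; zz < nz; zz++)
    for (int y = 0; y < ny; y++) {
      R_xlen_t base = (R_xlen_t)nx * (y + (R_xlen_t)ny * zz);
      for (int x = 0; x < nx; x++) f[x] = out[base + x];
      dt1d(f.data(), d.data(), nx, w2, v, z);
      for (int x = 0; x < nx; x++) out[base + x] = d[x];
    }
  // y pass
  w2 = spacing[1] * spacing[1];
  for (int zz = 0; zz < nz; zz++)
    for (int x = 0; x < nx; x++) {
      R_xlen_t base = x + (R_xlen_t)nx * ny * zz;
      for (int y = 0; y < ny; y++) f[y] = out[base + (R_xlen_t)nx * y];
      dt1d(f.data(), d.data(), ny, w2, v, z);
      for (int y = 0; y < ny; y++) out[base + (R_xlen_t)nx * y] = d[y];
    }
  // z pass
  w2 = spacing[2] * spacing[2];
  R_xlen_t stepz = (R_xlen_t)nx * ny;
  for (int y = 0; y < ny; y++)
    for (int x = 0; x < nx; x++) {
      R_xlen_t base = x + (R_xlen_t)nx * y;
      for (int zz = 0; zz < nz; zz++) f[zz] = out[base + stepz * zz];
      dt1d(f.data(), d.data(), nz, w2, v, z);
      for (int zz = 0; zz < nz; zz++) out[base + stepz * zz] = d[zz];
    }
  for (R_xlen_t i = 0; i < n; i++) if (out[i] >= INF) out[i] = R_PosInf;
  return out;
}

// Connected-component labelling (6- or 26-connectivity).
// [[Rcpp::export(name = ".label3d")]]
IntegerVector label3d(LogicalVector mask, IntegerVector dim, int connectivity) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> offs;
  std::vector<std::array<int,3>> doffs;
  for (int dz = -1; dz <= 1; dz++)
    for (int dy = -1; dy <= 1; dy++)
      for (int dx = -1; dx <= 1; dx++) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        doffs.push_back({dx, dy, dz});
      }
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; s++) {
    if (!mask[s] || lab[s]) continue;
    next++;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back(); stack.pop_back();
      int x = (int)(cur % nx);
      int y = (int)((cur / nx) % ny);
      int zz = (int)(cur / ((R_xlen_t)nx * ny));
      for (auto& d : doffs) {
        int x2 = x + d[0], y2 = y + d[1], z2 = zz + d[2];
        if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
          continue;
        R_xlen_t idx = x2 + (R_xlen_t)nx * (y2 + (R_xlen_t)ny * z2);
        if (mask[idx] && !lab[idx]) { lab[idx] = next; stack.push_back(idx); }
      }
    }
  }
  return lab;
}

static void conv1d_axis(std::vector<double>& vol, int nx, int ny, int nz,
                        int axis, const std::vector<double>& k) {
  int r = ((int)k.size() - 1) / 2;
  int nax = axis == 0 ? nx : (axis == 1 ? ny : nz);
  if (nax == 1) return;
  std::vector<double> line(nax), out(nax);
  R_xlen_t step = axis == 0 ? 1 : (axis == 1 ? (R_xlen_t)nx : (R_xlen_t)nx * ny);
  int n1 = axis == 0 ? ny : nx;
  int n2 = axis == 2 ? ny : nz;
  for (int j2 = 0; j2 < n2; j2++)
    for (int j1 = 0; j1 < n1; j1++) {
      R_xlen_t base;
      if (axis == 0) base = (R_xlen_t)nx * (j1 + (R_xlen_t)ny * j2);
      else if (axis == 1) base = j1 + (R_xlen_t)nx * ny * j2;
      else base = j1 + (R_xlen_t)nx * j2;
      for (int i = 0; i < nax; i++) line[i] = vol[base + step * i];
      for (int i = 0; i < nax; i++) {
        double acc = 0.0;
        for (int t = -r; t <= r; t++) {
          int idx = i + t;
          if (idx < 0) idx = -idx;                 // mirror boundary
          if (idx >= nax) idx = 2 * nax - 2 - idx;
          if (idx < 0) idx = 0;
          acc += line[idx] * k[t + r];
        }
        out[i] = acc;
      }
      for (int i = 0; i < nax; i++) vol[base + step * i] = out[i];
    }
}

// Separable Gaussian smoothing with per-axis sigma in voxel units.
// [[Rcpp::export(name = ".gauss3d")]]
NumericVector gauss3d(NumericVector img, IntegerVector dim,
                      NumericVector sigma) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> vol(img.begin(), img.end());
  for (int axis = 0; axis < 3; axis++) {
    double s = sigma[axis];
    if (s <= 0) continue;
    int r = std::max(1, (int)std::ceil(3.5 * s));
    std::vector<double> k(2 * r + 1);
    double sum = 0.0;
    for (int t = -r; t <= r; t++) {
      k[t + r] = std::exp(-0.5 * t * t / (s * s));
      sum += k[t + r];
    }
    for (auto& v : k) v /= sum;
    conv1d_axis(vol, nx, ny, nz, axis, k);
  }
  NumericVector out(n);
  std::copy(vol.begin(), vol.end(), out.begin());
  return out;
}

// Strict local maxima over the 26-neighbourhood, above an absolute threshold.
// Plateaus: a voxel qualifies if no neighbour exceeds it and it exceeds at
// least one neighbour (flat regions yield no seed).
// [[Rcpp::export(name = ".local_maxima3d")]]
LogicalVector local_maxima3d(NumericVector img, IntegerVector dim,
                             double threshold) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n, false);
  for (int zz = 0; zz < nz; zz++)
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++) {
        R_xlen_t i = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * zz);
        double v = img[i];
        if (v < threshold) continue;
        bool isMax = true, strict = false;
        for (int dz = -1; dz <= 1 && isMax; dz++)
          for (int dy = -1; dy <= 1 && isMax; dy++)
            for (int dx = -1; dx <= 1; dx++) {
              if (!dx && !dy && !dz) continue;
              int x2 = x + dx, y2 = y + dy, z2 = zz + dz;
              if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny ||
                  z2 < 0 || z2 >= nz) continue;
              double w = img[x2 + (R_xlen_t)nx * (y2 + (R_xlen_t)ny * z2)];
              if (w > v) { isMax = false; break; }
              if (w < v) strict = true;
            }
        if (isMax && strict) out[i] = true;
      }
  return out;
}

// Trilinear sampling of a volume at fractional voxel coordinates (0-based).
// Out-of-range points are clamped to the border.
// [[Rcpp::export(name = ".trilinear_sample")]]
NumericVector trilinear_sample(NumericVector img, IntegerVector dim,
                               NumericMatrix pts) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int np = pts.nrow();
  NumericVector out(np);
  for (int p = 0; p < np; p++) {
    double x = pts(p, 0), y = pts(p, 1), zz = pts(p, 2);
    if (x < 0) x = 0; if (x > nx - 1) x = nx - 1;
    if (y < 0) y = 0; if (y > ny - 1) y = ny - 1;
    if (zz < 0) zz = 0; if (zz > nz - 1) zz = nz - 1;
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y),
        z0 = (int)std::floor(zz);
    int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1),
        z1 = std::min(z0 + 1, nz - 1);
    double fx = x - x0, fy = y - y0, fz = zz - z0;
    #define V(a,b,c) img[(a) + (R_xlen_t)nx * ((b) + (R_xlen_t)ny * (c))]
    double c00 = V(x0,y0,z0) * (1-fx) + V(x1,y0,z0) * fx;
    double c10 = V(x0,y1,z0) * (1-fx) + V(x1,y1,z0) * fx;
    double c01 = V(x0,y0,z1) * (1-fx) + V(x1,y0,z1) * fx;
    double c11 = V(x0,y1,z1) * (1-fx) + V(x1,y1,z1) * fx;
    #undef V
    double c0 = c00 * (1-fy) + c10 * fy;
    double c1 = c01 * (1-fy) + c11 * fy;
    out[p] = c0 * (1-fz) + c1 * fz;
  }
  return out;
}

// Draw polyline points into a volume as TRUE voxels (dense sampling done by
// the caller); pts are fractional voxel coordinates, rounded to nearest voxel.
// [[Rcpp::export(name = ".stamp_points")]]
LogicalVector stamp_points(LogicalVector vol, IntegerVector dim,
                           NumericMatrix pts) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalVector out = clone(vol);
  for (int p = 0; p < pts.nrow(); p++) {
    int x = (int)std::lround(pts(p, 0));
    int y = (int)std::lround(pts(p, 1));
    int zz = (int)std::lround(pts(p, 2));
    if (x < 0 || x >= nx || y < 0 || y >= ny || zz < 0 || zz >= nz) continue;
    out[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * zz)] = true;
  }
  return out;
}
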