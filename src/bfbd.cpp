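// Robust (Cauchy-IRLS) sliding-window linear background estimation along z,
// the inner loop of the foreground/background discrimination de-noiser.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// img: column-major volume; alpha: per-plane conversion factor; beta:
// offset. Returns the per-voxel background estimate.
// [[Rcpp::export(name = ".bfbd_background")]]
NumericVector bfbd_background(NumericVector img, IntegerVector dim,
                              int window, NumericVector alpha, double beta,
                              int iters) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t ncol = (R_xlen_t)nx * ny;
  NumericVector out((R_xlen_t)ncol * nz);
  if (window > nz) window = nz;
  int half = window / 2;
  std::vector<double> y(window), w(window), xv(window), sc(window);
  for (R_xlen_t c = 0; c < ncol; c++) {
    for (int z = 0; z < nz; z++) {
      int z0 = z - half;
      if (z0 < 0) z0 = 0;
      if (z0 > nz - window) z0 = nz - window;
      for (int t = 0; t < window; t++) {
        xv[t] = z0 + t;
        y[t] = img[c + ncol * (z0 + t)];
        double v = alpha[z0 + t] * (y[t] - beta);
        sc[t] = std::sqrt(v > 1e-6 ? v : 1e-6);
        w[t] = 1.0;
      }
      double slope = 0.0, inter = 0.0;
      for (int it = 0; it < iters; it++) {
        double sw = 0, sx = 0, sy = 0, sxx = 0, sxy = 0;
        for (int t = 0; t < window; t++) {
          sw += w[t]; sx += w[t] * xv[t]; sy += w[t] * y[t];
          sxx += w[t] * xv[t] * xv[t]; sxy += w[t] * xv[t] * y[t];
        }
        double det = sw * sxx - sx * sx;
        if (std::fabs(det) < 1e-12) break;
        slope = (sw * sxy - sx * sy) / det;
        inter = (sy * sxx - sx * sxy) / det;
        for (int t = 0; t < window; t++) {
          double r = (y[t] - inter - slope * xv[t]) / (2.385 * sc[t]);
          w[t] = 1.0 / (1.0 + r * r);
        }
      }
      out[c + ncol * z] = inter + slope * z;
    }
  }
  return out;
}
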