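// Grey-level co-occurrence accumulation in 3D and direct normalized
// cross-correlation over integer shifts.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Accumulate co-occurrence counts over the given displacement vectors.
// `q` holds quantized levels 0..(nlev-1), or -1 outside the region of
// interest. Counts are symmetrized (both orders of each pair).
// [[Rcpp::export(name = ".glcm3d")]]
NumericMatrix glcm3d(IntegerVector q, IntegerVector dim, int nlev,
                     IntegerMatrix offsets) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix counts(nlev, nlev);
  for (int o = 0; o < offsets.nrow(); o++) {
    int dx = offsets(o, 0), dy = offsets(o, 1), dz = offsets(o, 2);
    for (int z = 0; z < nz; z++) {
      int z2 = z + dz;
      if (z2 < 0 || z2 >= nz) continue;
      for (int y = 0; y < ny; y++) {
        int y2 = y + dy;
        if (y2 < 0 || y2 >= ny) continue;
        for (int x = 0; x < nx; x++) {
          int x2 = x + dx;
          if (x2 < 0 || x2 >= nx) continue;
          int a = q[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)];
          int b = q[x2 + (R_xlen_t)nx * (y2 + (R_xlen_t)ny * z2)];
          if (a < 0 || b < 0) continue;
          counts(a, b) += 1.0;
          counts(b, a) += 1.0;
        }
      }
    }
  }
  return counts;
}

// Normalized cross-correlation of `b` placed at integer offsets relative to
// `a`, over the voxels where the two grids overlap. Returns an array of
// correlations with dim = lengths of the shift ranges; overlaps smaller than
// `minOverlap` voxels yield NA.
// [[Rcpp::export(name = ".ncc_search")]]
NumericVector ncc_search(NumericVector a, IntegerVector adim,
                         NumericVector b, IntegerVector bdim,
                         IntegerVector sx, IntegerVector sy, IntegerVector sz,
                         double minOverlap) {
  int ax = adim[0], ay = adim[1], az = adim[2];
  int bx = bdim[0], by = bdim[1], bz = bdim[2];
  NumericVector out((R_xlen_t)sx.size() * sy.size() * sz.size());
  R_xlen_t oi = 0;
  for (int ks = 0; ks < sz.size(); ks++)
    for (int js = 0; js < sy.size(); js++)
      for (int is = 0; is < sx.size(); is++, oi++) {
        int ox = sx[is], oy = sy[js], oz = sz[ks];
        int x0 = std::max(0, ox), x1 = std::min(ax, bx + ox);
        int y0 = std::max(0, oy), y1 = std::min(ay, by + oy);
        int z0 = std::max(0, oz), z1 = std::min(az, bz + oz);
        double nvox = (double)std::max(0, x1 - x0) *
                      std::max(0, y1 - y0) * std::max(0, z1 - z0);
        if (nvox < minOverlap) { out[oi] = NA_REAL; continue; }
        double sa = 0, sb = 0, saa = 0, sbb = 0, sab = 0;
        for (int z = z0; z < z1; z++)
          for (int y = y0; y < y1; y++)
            for (int x = x0; x < x1; x++) {
              double va = a[x + (R_xlen_t)ax * (y + (R_xlen_t)ay * z)];
              double vb = b[(x - ox) + (R_xlen_t)bx *
                            ((y - oy) + (R_xlen_t)by * (z - oz))];
              sa += va; sb += vb; saa += va * va; sbb += vb * vb;
              sab += va * vb;
            }
        double cov = sab - sa * sb / nvox;
        double vara = saa - sa * sa / nvox;
        double varb = sbb - sb * sb / nvox;
        if (vara <= 0 || varb <= 0) { out[oi] = NA_REAL; continue; }
        out[oi] = cov / std::sqrt(vara * varb);
      }
  return out;
}
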