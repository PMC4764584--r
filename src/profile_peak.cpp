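// Normal-line profile peak search used by active-mesh gradient tuning:
// for each vertex, sample a scalar field along its normal at the given
// offsets and return the parabolic-refined offset of the profile maximum
// (0 when the profile is flat).
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double sample3(const double* vol, int nx, int ny, int nz,
                             double x, double y, double z) {
  if (x < 0) x = 0; if (x > nx - 1) x = nx - 1;
  if (y < 0) y = 0; if (y > ny - 1) y = ny - 1;
  if (z < 0) z = 0; if (z > nz - 1) z = nz - 1;
  int x0 = (int)x, y0 = (int)y, z0 = (int)z;
  int x1 = x0 + 1 < nx ? x0 + 1 : x0;
  int y1 = y0 + 1 < ny ? y0 + 1 : y0;
  int z1 = z0 + 1 < nz ? z0 + 1 : z0;
  double fx = x - x0, fy = y - y0, fz = z - z0;
  #define V(a,b,c) vol[(a) + (R_xlen_t)nx * ((b) + (R_xlen_t)ny * (c))]
  double c00 = V(x0,y0,z0) * (1-fx) + V(x1,y0,z0) * fx;
  double c10 = V(x0,y1,z0) * (1-fx) + V(x1,y1,z0) * fx;
  double c01 = V(x0,y0,z1) * (1-fx) + V(x1,y0,z1) * fx;
  double c11 = V(x0,y1,z1) * (1-fx) + V(x1,y1,z1) * fx;
  #undef V
  double c0 = c00 * (1-fy) + c10 * fy;
  double c1 = c01 * (1-fy) + c11 * fy;
  return c0 * (1-fz) + c1 * fz;
}

// verts in µm, normals unit (µm space), offsets in µm; spacing converts to
// voxel coordinates. Returns per-vertex offset of the profile maximum.
// [[Rcpp::export(name = ".profile_peak")]]
NumericVector profile_peak(NumericVector vol, IntegerVector dim,
                           NumericMatrix verts, NumericMatrix normals,
                           NumericVector offsets, NumericVector spacing,
                           double minProminence) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int nv = verts.nrow(), no = offsets.size();
  NumericVector out(nv);
  const double* p = vol.begin();
  std::vector<double> prof(no);
  for (int v = 0; v < nv; v++) {
    double mx = -1e300, mn = 1e300;
    int best = 0;
    for (int o = 0; o < no; o++) {
      double x = (verts(v,0) + offsets[o] * normals(v,0)) / spacing[0];
      double y = (verts(v,1) + offsets[o] * normals(v,1)) / spacing[1];
      double z = (verts(v,2) + offsets[o] * normals(v,2)) / spacing[2];
      double s = sample3(p, nx, ny, nz, x, y, z);
      prof[o] = s;
      if (s > mx) { mx = s; best = o; }
      if (s < mn) mn = s;
    }
    if (mx - mn < 1e-9 || mx < minProminence) { out[v] = 0.0; continue; }
    double shift = offsets[best];
    if (best > 0 && best < no - 1) {
      double ym = prof[best - 1], y0 = prof[best], yp = prof[best + 1];
      double den = ym - 2 * y0 + yp;
      if (std::fabs(den) > 1e-12) {
        double corr = 0.5 * (ym - yp) / den;
        if (std::fabs(corr) <= 1.0)
          shift += corr * (offsets[1] - offsets[0]);
      }
    }
    out[v] = shift;
  }
  return out;
}

// area-weighted outward vertex normals of an oriented triangle mesh
// [[Rcpp::export(name = ".vertex_normals")]]
NumericMatrix vertex_normals(NumericMatrix V, IntegerMatrix T) {
  int nv = V.nrow(), nt = T.nrow();
  NumericMatrix N(nv, 3);
  for (int t = 0; t < nt; t++) {
    int a = T(t,0) - 1, b = T(t,1) - 1, c = T(t,2) - 1;
    double ux = V(b,0)-V(a,0), uy = V(b,1)-V(a,1), uz = V(b,2)-V(a,2);
    double wx = V(c,0)-V(a,0), wy = V(c,1)-V(a,1), wz = V(c,2)-V(a,2);
    double nx = uy*wz - uz*wy, ny = uz*wx - ux*wz, nz = ux*wy - uy*wx;
    N(a,0)+=nx; N(a,1)+=ny; N(a,2)+=nz;
    N(b,0)+=nx; N(b,1)+=ny; N(b,2)+=nz;
    N(c,0)+=nx; N(c,1)+=ny; N(c,2)+=nz;
  }
  for (int v = 0; v < nv; v++) {
    double len = std::sqrt(N(v,0)*N(v,0)+N(v,1)*N(v,1)+N(v,2)*N(v,2));
    if (len < 1e-12) len = 1.0;
    N(v,0)/=len; N(v,1)/=len; N(v,2)/=len;
  }
  return N;
}

// per-vertex mean of the 1-ring neighbours given a directed edge list
// [[Rcpp::export(name = ".neighbor_mean")]]
NumericMatrix neighbor_mean(NumericMatrix V, IntegerVector from,
                            IntegerVector to) {
  int nv = V.nrow();
  NumericMatrix S(nv, 3);
  std::vector<int> deg(nv, 0);
  for (int e = 0; e < from.size(); e++) {
    int a = from[e] - 1, b = to[e] - 1;
    S(a,0) += V(b,0); S(a,1) += V(b,1); S(a,2) += V(b,2);
    deg[a]++;
  }
  for (int v = 0; v < nv; v++) {
    if (deg[v] > 0) { S(v,0)/=deg[v]; S(v,1)/=deg[v]; S(v,2)/=deg[v]; }
    else { S(v,0)=V(v,0); S(v,1)=V(v,1); S(v,2)=V(v,2); }
  }
  return S;
}

// in-place assignment into an integer vector (used for the shared
// occupancy grid, avoiding a full-array copy per active-mesh step)
// [[Rcpp::export(name = ".assign_int")]]
void assign_int(IntegerVector v, IntegerVector idx, int val) {
  for (R_xlen_t i = 0; i < idx.size(); i++) v[idx[i] - 1] = val;
}
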