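// Isosurface extraction by marching tetrahedra (6-tetrahedron cube
// decomposition, consistent face diagonals between neighbouring cubes) and
// parity-fill voxelization of closed triangle meshes.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

namespace {

struct MeshAcc {
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;                       // 0-based vertex triples
  std::unordered_map<uint64_t, int> edgeVert;           // interpolated vertex per edge
};

// cube corner offsets (x, y, z)
static const int CORNER[8][3] = {
  {0,0,0},{1,0,0},{1,1,0},{0,1,0},{0,0,1},{1,0,1},{1,1,1},{0,1,1}};
// 6 tetrahedra sharing the 0-6 diagonal
static const int TETS[6][4] = {
  {0,1,2,6},{0,2,3,6},{0,3,7,6},{0,7,4,6},{0,4,5,6},{0,5,1,6}};

inline uint64_t edgeKey(uint64_t a, uint64_t b) {
  if (a > b) std::swap(a, b);
  return a * 20000000ULL + b;
}

int interpVertex(MeshAcc& m, uint64_t ga, uint64_t gb,
                 const double* pa, const double* pb,
                 double va, double vb, double level) {
  uint64_t key = edgeKey(ga, gb);
  auto it = m.edgeVert.find(key);
  if (it != m.edgeVert.end()) return it->second;
  double t = (level - va) / (vb - va);
  if (t < 0) t = 0; if (t > 1) t = 1;
  m.vx.push_back(pa[0] + t * (pb[0] - pa[0]));
  m.vy.push_back(pa[1] + t * (pb[1] - pa[1]));
  m.vz.push_back(pa[2] + t * (pb[2] - pa[2]));
  int id = (int)m.vx.size() - 1;
  m.edgeVert[key] = id;
  return id;
}

// Emit one triangle oriented so its normal points away from the inside.
void emitTri(MeshAcc& m, int a, int b, int c, const double* inCentroid) {
  double ax = m.vx[a], ay = m.vy[a], az = m.vz[a];
  double ux = m.vx[b] - ax, uy = m.vy[b] - ay, uz = m.vz[b] - az;
  double wx = m.vx[c] - ax, wy = m.vy[c] - ay, wz = m.vz[c] - az;
  double nx = uy * wz - uz * wy;
  double ny = uz * wx - ux * wz;
  double nz = ux * wy - uy * wx;
  double cx = (ax + m.vx[b] + m.vx[c]) / 3.0 - inCentroid[0];
  double cy = (ay + m.vy[b] + m.vy[c]) / 3.0 - inCentroid[1];
  double cz = (az + m.vz[b] + m.vz[c]) / 3.0 - inCentroid[2];
  if (nx * cx + ny * cy + nz * cz < 0) std::swap(b, c);
  m.tri.push_back(a); m.tri.push_back(b); m.tri.push_back(c);
}

} // namespace

// Marching tetrahedra over a scalar field (column-major, dim = nx,ny,nz).
// Vertices returned in voxel coordinates (0-based, fractional); the caller
// scales to micrometres. The field is conceptually padded with `pad` below
// the level so border-touching components are capped.
// [[Rcpp::export(name = ".march_tets")]]
List march_tets(NumericVector field, IntegerVector dim, double level) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  // padded grid of size (nx+2, ny+2, nz+2); value at padded coord
  int px = nx + 2, py = ny + 2, pz = nz + 2;
  double pad = level - 1.0;
  MeshAcc m;
  auto val = [&](int x, int y, int z) -> double {
    int xi = x - 1, yi = y - 1, zi = z - 1;
    if (xi < 0 || xi >= nx || yi < 0 || yi >= ny || zi < 0 || zi >= nz)
      return pad;
    return field[xi + (R_xlen_t)nx * (yi + (R_xlen_t)ny * zi)];
  };
  double cpos[8][3]; double cval[8]; uint64_t gid[8];
  for (int z = 0; z < pz - 1; z++)
    for (int y = 0; y < py - 1; y++)
      for (int x = 0; x < px - 1; x++) {
        bool any = false, all = true;
        for (int c = 0; c < 8; c++) {
          int cx = x + CORNER[c][0], cy = y + CORNER[c][1],
              cz = z + CORNER[c][2];
          cval[c] = val(cx, cy, cz);
          cpos[c][0] = cx - 1.0; cpos[c][1] = cy - 1.0; cpos[c][2] = cz - 1.0;
          gid[c] = (uint64_t)cx + (uint64_t)px * ((uint64_t)cy +
                   (uint64_t)py * (uint64_t)cz);
          if (cval[c] > level) any = true; else all = false;
        }
        if (!any || all) continue;
        for (int t = 0; t < 6; t++) {
          int id[4] = {TETS[t][0], TETS[t][1], TETS[t][2], TETS[t][3]};
          int in[4], out[4]; int nin = 0, nout = 0;
          for (int c = 0; c < 4; c++) {
            if (cval[id[c]] > level) in[nin++] = id[c];
            else out[nout++] = id[c];
          }
          if (nin == 0 || nin == 4) continue;
          double ic[3] = {0, 0, 0};
          for (int c = 0; c < nin; c++)
            for (int a = 0; a < 3; a++) ic[a] += cpos[in[c]][a] / nin;
          if (nin == 1) {
            int a = in[0];
            int e0 = interpVertex(m, gid[a], gid[out[0]], cpos[a],
                                  cpos[out[0]], cval[a], cval[out[0]], level);
            int e1 = interpVertex(m, gid[a], gid[out[1]], cpos[a],
                                  cpos[out[1]], cval[a], cval[out[1]], level);
            int e2 = interpVertex(m, gid[a], gid[out[2]], cpos[a],
                                  cpos[out[2]], cval[a], cval[out[2]], level);
            emitTri(m, e0, e1, e2, ic);
          } else if (nin == 3) {
            int a = out[0];
            int e0 = interpVertex(m, gid[a], gid[in[0]], cpos[a],
                                  cpos[in[0]], cval[a], cval[in[0]], level);
            int e1 = interpVertex(m, gid[a], gid[in[1]], cpos[a],
                                  cpos[in[1]], cval[a], cval[in[1]], level);
            int e2 = interpVertex(m, gid[a], gid[in[2]], cpos[a],
                                  cpos[in[2]], cval[a], cval[in[2]], level);
            emitTri(m, e0, e1, e2, ic);
          } else { // nin == 2
            int a = in[0], b = in[1], c = out[0], d = out[1];
            int eac = interpVertex(m, gid[a], gid[c], cpos[a], cpos[c],
                                   cval[a], cval[c], level);
            int ead = interpVertex(m, gid[a], gid[d], cpos[a], cpos[d],
                                   cval[a], cval[d], level);
            int ebc = interpVertex(m, gid[b], gid[c], cpos[b], cpos[c],
                                   cval[b], cval[c], level);
            int ebd = interpVertex(m, gid[b], gid[d], cpos[b], cpos[d],
                                   cval[b], cval[d], level);
            emitTri(m, eac, ead, ebd, ic);
            emitTri(m, eac, ebd, ebc, ic);
          }
        }
      }
  int nv = (int)m.vx.size();
  NumericMatrix verts(nv, 3);
  for (int i = 0; i < nv; i++) {
    verts(i, 0) = m.vx[i]; verts(i, 1) = m.vy[i]; verts(i, 2) = m.vz[i];
  }
  int nt = (int)m.tri.size() / 3;
  IntegerMatrix tris(nt, 3);
  for (int i = 0; i < nt; i++) {
    tris(i, 0) = m.tri[3 * i] + 1;       // 1-based for R
    tris(i, 1) = m.tri[3 * i + 1] + 1;
    tris(i, 2) = m.tri[3 * i + 2] + 1;
  }
  return List::create(_["vertices"] = verts, _["triangles"] = tris);
}

// Voxelization of a closed oriented mesh. Vertices in fractional voxel
// coordinates; a voxel is inside if its centre lies inside the mesh.
// With signedFill, crossings carry the sign of the triangle normal's z
// component and the interior is where the winding count is positive, which
// is robust to locally interpenetrating (but consistently oriented)
// surfaces; otherwise even-odd parity is used.
// [[Rcpp::export(name = ".voxelize_mesh")]]
LogicalVector voxelize_mesh(NumericMatrix verts, IntegerMatrix tris,
                            IntegerVector dim, bool signedFill) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n, false);
  // z-crossings per (x, y) column: z position and sign
  std::vector<std::vector<std::pair<double, int>>> cross((size_t)nx * ny);
  const double eps = 1e-9;
  for (int t = 0; t < tris.nrow(); t++) {
    int a = tris(t, 0) - 1, b = tris(t, 1) - 1, c = tris(t, 2) - 1;
    double ax = verts(a,0), ay = verts(a,1), az = verts(a,2);
    double bx = verts(b,0), by = verts(b,1), bz = verts(b,2);
    double cx = verts(c,0), cy = verts(c,1), cz = verts(c,2);
    int x0 = (int)std::ceil(std::min(ax, std::min(bx, cx)) - eps);
    int x1 = (int)std::floor(std::max(ax, std::max(bx, cx)) + eps);
    int y0 = (int)std::ceil(std::min(ay, std::min(by, cy)) - eps);
    int y1 = (int)std::floor(std::max(ay, std::max(by, cy)) + eps);
    x0 = std::max(x0, 0); x1 = std::min(x1, nx - 1);
    y0 = std::max(y0, 0); y1 = std::min(y1, ny - 1);
    double d = (by - ay) * (cx - ax) - (bx - ax) * (cy - ay);
    if (std::fabs(d) < 1e-14) continue;     // degenerate in projection
    // +1 where the ray enters the solid (outward normal z < 0, i.e. d > 0)
    int sgn = d > 0 ? 1 : -1;
    for (int y = y0; y <= y1; y++)
      for (int x = x0; x <= x1; x++) {
        // jittered ray position avoids exact vertex/edge hits
        double rx = x + 1.23456789e-6, ry = y + 2.3456789e-6;
        double w1 = ((by - ay) * (rx - ax) - (bx - ax) * (ry - ay)) / d;
        double w0 = ((ry - ay) * (cx - ax) - (rx - ax) * (cy - ay)) / d;
        // barycentric: p = a + w0*(b-a) + w1*(c-a)
        if (w0 < 0 || w1 < 0 || w0 + w1 > 1) continue;
        double zhit = az + w0 * (bz - az) + w1 * (cz - az);
        cross[(size_t)x + (size_t)nx * y].push_back({zhit, sgn});
      }
  }
  for (int y = 0; y < ny; y++)
    for (int x = 0; x < nx; x++) {
      auto& cz = cross[(size_t)x + (size_t)nx * y];
      if (cz.empty()) continue;
      std::sort(cz.begin(), cz.end());
      if (!signedFill) {
        for (size_t i = 0; i + 1 < cz.size(); i += 2) {
          int zlo = (int)std::ceil(cz[i].first);
          int zhi = (int)std::floor(cz[i + 1].first);
          zlo = std::max(zlo, 0); zhi = std::min(zhi, nz - 1);
          for (int zz = zlo; zz <= zhi; zz++)
            out[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * zz)] = true;
        }
      } else {
        int wind = 0;
        for (size_t i = 0; i < cz.size(); i++) {
          int prev = wind;
          wind += cz[i].second;
          bool insideSeg = (prev <= 0 && wind > 0) || prev > 0;
          if (wind > 0 && i + 1 < cz.size()) {
            (void)insideSeg;
            int zlo = (int)std::ceil(cz[i].first);
            int zhi = (int)std::floor(cz[i + 1].first);
            zlo = std::max(zlo, 0); zhi = std::min(zhi, nz - 1);
            for (int zz = zlo; zz <= zhi; zz++)
              out[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * zz)] = true;
          }
        }
      }
    }
  return out;
}
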