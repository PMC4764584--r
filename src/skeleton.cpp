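// Curve skeletonization by sequential deletion of simple border voxels in
// increasing distance-transform order, preserving curve end points. A voxel
// is simple (its removal preserves topology) iff its 3x3x3 neighbourhood has
// exactly one 26-connected object component and exactly one 6-connected
// background component that touches a face neighbour.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

// offsets of the 26 neighbours as (dx, dy, dz)
struct Nbh {
  int dx[26], dy[26], dz[26];
  Nbh() {
    int k = 0;
    for (int z = -1; z <= 1; z++)
      for (int y = -1; y <= 1; y++)
        for (int x = -1; x <= 1; x++) {
          if (!x && !y && !z) continue;
          dx[k] = x; dy[k] = y; dz[k] = z; k++;
        }
  }
};
static const Nbh NB;

inline int cellIndex(int x, int y, int z) { return (x+1) + 3*((y+1) + 3*(z+1)); }

// number of 26-connected components among object cells of the 3x3x3
// neighbourhood (centre excluded)
int objComponents(const bool* nb) {
  bool seen[27] = {false};
  int comps = 0;
  for (int i = 0; i < 27; i++) {
    if (i == 13 || !nb[i] || seen[i]) continue;
    comps++;
    std::vector<int> stack{i};
    seen[i] = true;
    while (!stack.empty()) {
      int c = stack.back(); stack.pop_back();
      int cx = c % 3 - 1, cy = (c / 3) % 3 - 1, cz = c / 9 - 1;
      for (int k = 0; k < 26; k++) {
        int x2 = cx + NB.dx[k], y2 = cy + NB.dy[k], z2 = cz + NB.dz[k];
        if (x2 < -1 || x2 > 1 || y2 < -1 || y2 > 1 || z2 < -1 || z2 > 1)
          continue;
        int c2 = cellIndex(x2, y2, z2);
        if (c2 == 13 || !nb[c2] || seen[c2]) continue;
        seen[c2] = true;
        stack.push_back(c2);
      }
    }
  }
  return comps;
}

// number of 6-connected background components within the 18-neighbourhood
// (cells at Chebyshev distance 1 with at most two nonzero offsets) that
// contain at least one face neighbour
int bgComponents(const bool* nb) {
  auto inN18 = [](int x, int y, int z) {
    return std::abs(x) + std::abs(y) + std::abs(z) <= 2 &&
           !(x == 0 && y == 0 && z == 0);
  };
  bool seen[27] = {false};
  int comps = 0;
  static const int FACES[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},
                                  {0,0,1},{0,0,-1}};
  for (auto& f : FACES) {
    int c = cellIndex(f[0], f[1], f[2]);
    if (nb[c] || seen[c]) continue;
    comps++;
    std::vector<int> stack{c};
    seen[c] = true;
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      int cx = cur % 3 - 1, cy = (cur / 3) % 3 - 1, cz = cur / 9 - 1;
      for (auto& f2 : FACES) {
        int x2 = cx + f2[0], y2 = cy + f2[1], z2 = cz + f2[2];
        if (!inN18(x2, y2, z2)) continue;
        int c2 = cellIndex(x2, y2, z2);
        if (nb[c2] || seen[c2]) continue;
        seen[c2] = true;
        stack.push_back(c2);
      }
    }
  }
  return comps;
}

} // namespace

// [[Rcpp::export(name = ".thin3d")]]
LogicalVector thin3d(LogicalVector mask, IntegerVector dim,
                     NumericVector edtsq) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector obj = clone(mask);
  typedef std::pair<double, R_xlen_t> QE;  // (distance, index)
  std::priority_queue<QE, std::vector<QE>, std::greater<QE>> pq;
  std::vector<char> queued(n, 0);
  auto idx3 = [&](int x, int y, int z) {
    return (R_xlen_t)x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
  };
  auto isBorder = [&](int x, int y, int z) {
    static const int F[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},
                                {0,0,1},{0,0,-1}};
    for (auto& f : F) {
      int x2 = x + f[0], y2 = y + f[1], z2 = z + f[2];
      if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
        return true;                        // volume border counts as bg
      if (!obj[idx3(x2, y2, z2)]) return true;
    }
    return false;
  };
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++) {
        R_xlen_t i = idx3(x, y, z);
        if (obj[i] && isBorder(x, y, z)) { pq.push({edtsq[i], i}); queued[i] = 1; }
      }
  bool nbv[27];
  while (!pq.empty()) {
    R_xlen_t i = pq.top().second; pq.pop();
    queued[i] = 0;
    if (!obj[i]) continue;
    int x = (int)(i % nx), y = (int)((i / nx) % ny),
        z = (int)(i / ((R_xlen_t)nx * ny));
    if (!isBorder(x, y, z)) continue;
    int nObj = 0;
    for (int c = 0; c < 27; c++) {
      int cx = x + (c % 3 - 1), cy = y + ((c / 3) % 3 - 1), cz = z + (c / 9 - 1);
      bool v = false;
      if (cx >= 0 && cx < nx && cy >= 0 && cy < ny && cz >= 0 && cz < nz)
        v = obj[idx3(cx, cy, cz)];
      nbv[c] = v;
      if (v && c != 13) nObj++;
    }
    if (nObj <= 1) continue;                // curve end point: keep
    if (objComponents(nbv) != 1) continue;  // not simple
    if (bgComponents(nbv) != 1) continue;
    obj[i] = false;                         // delete
    for (int k = 0; k < 26; k++) {
      int x2 = x + NB.dx[k], y2 = y + NB.dy[k], z2 = z + NB.dz[k];
      if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
        continue;
      R_xlen_t j = idx3(x2, y2, z2);
      if (obj[j] && !queued[j]) { pq.push({edtsq[j], j}); queued[j] = 1; }
    }
  }
  return obj;
}
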