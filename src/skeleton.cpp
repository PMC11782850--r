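#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

// 3D medial-curve thinning. A voxel may be deleted only if it is a simple
// point (deletion preserves topology) and not a curve endpoint. Simplicity is
// tested with the Bertrand-Malandain characterization:
//   * the foreground voxels of the 26-neighbourhood form exactly one
//     26-connected component, and
//   * the background voxels of the 18-neighbourhood that are 6-adjacent to
//     the center form exactly one 6-connected component.
// Deletion proceeds in six directional subiterations; candidates collected in
// parallel are deleted sequentially with a re-check, so topology is preserved
// exactly.

static inline int noff(int dx, int dy, int dz) {
  return (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1);
}

// nb: 27 bools, center at index 13.
static int count_fg_neighbors(const bool* nb) {
  int c = 0;
  for (int i = 0; i < 27; i++)
    if (i != 13 && nb[i]) c++;
  return c;
}

static bool is_simple(const bool* nb) {
  // --- condition 1: one 26-component of foreground in N26* ---
  int comp[27];
  for (int i = 0; i < 27; i++) comp[i] = -1;
  int ncomp = 0;
  int stack[27];
  for (int s = 0; s < 27; s++) {
    if (s == 13 || !nb[s] || comp[s] >= 0) continue;
    if (ncomp == 1) return false;  // a second component exists
    comp[s] = ncomp;
    int top = 0;
    stack[top++] = s;
    while (top > 0) {
      int cur = stack[--top];
      int cx = cur % 3, cy = (cur / 3) % 3, cz = cur / 9;
      for (int q = 0; q < 27; q++) {
        if (q == 13 || !nb[q] || comp[q] >= 0) continue;
        int qx = q % 3, qy = (q / 3) % 3, qz = q / 9;
        if (std::abs(qx - cx) <= 1 && std::abs(qy - cy) <= 1 &&
            std::abs(qz - cz) <= 1) {
          comp[q] = ncomp;
          stack[top++] = q;
        }
      }
    }
    ncomp++;
  }
  if (ncomp != 1) return false;

  // --- condition 2: one 6-component of background in N18 touching a face ---
  // N18 = offsets with at most two nonzero coordinates.
  bool in18[27];
  for (int i = 0; i < 27; i++) {
    int x = i % 3 - 1, y = (i / 3) % 3 - 1, z = i / 9 - 1;
    int nz = (x != 0) + (y != 0) + (z != 0);
    in18[i] = (i != 13) && nz <= 2;
  }
  for (int i = 0; i < 27; i++) comp[i] = -1;
  int nbgcomp = 0;
  for (int s = 0; s < 27; s++) {
    if (!in18[s] || nb[s] || comp[s] >= 0) continue;
    // flood this background component under 6-adjacency within N18
    bool touches_face = false;
    comp[s] = 1;
    int top = 0;
    stack[top++] = s;
    while (top > 0) {
      int cur = stack[--top];
      int cx = cur % 3 - 1, cy = (cur / 3) % 3 - 1, cz = cur / 9 - 1;
      if (std::abs(cx) + std::abs(cy) + std::abs(cz) == 1) touches_face = true;
      static const int fdx[6] = {1, -1, 0, 0, 0, 0};
      static const int fdy[6] = {0, 0, 1, -1, 0, 0};
      static const int fdz[6] = {0, 0, 0, 0, 1, -1};
      for (int k = 0; k < 6; k++) {
        int qx = cx + fdx[k], qy = cy + fdy[k], qz = cz + fdz[k];
        if (qx < -1 || qx > 1 || qy < -1 || qy > 1 || qz < -1 || qz > 1)
          continue;
        int q = noff(qx, qy, qz);
        if (!in18[q] || nb[q] || comp[q] >= 0) continue;
        comp[q] = 1;
        stack[top++] = q;
      }
    }
    if (touches_face) {
      nbgcomp++;
      if (nbgcomp > 1) return false;
    }
  }
  return nbgcomp == 1;
}

static void gather(const std::vector<char>& img, int nx, int ny, int nz,
                   int x, int y, int z, bool* nb) {
  for (int dz = -1; dz <= 1; dz++)
    for (int dy = -1; dy <= 1; dy++)
      for (int dx = -1; dx <= 1; dx++) {
        int xx = x + dx, yy = y + dy, zz = z + dz;
        bool v = false;
        if (xx >= 0 && xx < nx && yy >= 0 && yy < ny && zz >= 0 && zz < nz)
          v = img[(size_t)xx + (size_t)nx * (yy + (size_t)ny * zz)] != 0;
        nb[noff(dx, dy, dz)] = v;
      }
}

// [[Rcpp::export]]
LogicalVector cpp_skeletonize(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<char> img(n);
  for (size_t i = 0; i < n; i++) img[i] = mask[i] ? 1 : 0;

  static const int bdx[6] = {0, 0, 0, 0, -1, 1};
  static const int bdy[6] = {0, 0, -1, 1, 0, 0};
  static const int bdz[6] = {-1, 1, 0, 0, 0, 0};

  bool nb[27];
  std::vector<size_t> cand;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; d++) {
      cand.clear();
      for (int z = 0; z < nz; z++)
        for (int y = 0; y < ny; y++)
          for (int x = 0; x < nx; x++) {
            size_t i = (size_t)x + (size_t)nx * (y + (size_t)ny * z);
            if (!img[i]) continue;
            int xx = x + bdx[d], yy = y + bdy[d], zz = z + bdz[d];
            bool border =
                (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 ||
                 zz >= nz) ||
                !img[(size_t)xx + (size_t)nx * (yy + (size_t)ny * zz)];
            if (!border) continue;
            gather(img, nx, ny, nz, x, y, z, nb);
            if (count_fg_neighbors(nb) < 2) continue;  // endpoint or isolated
            if (is_simple(nb)) cand.push_back(i);
          }
      // sequential deletion: re-check simplicity only (endpoint status was
      // fixed at collection time, so voxels that become line ends mid-pass
      // are still removed and no spurs are left behind)
      for (size_t c = 0; c < cand.size(); c++) {
        size_t i = cand[c];
        int x = (int)(i % nx);
        int y = (int)((i / nx) % ny);
        int z = (int)(i / ((size_t)nx * ny));
        gather(img, nx, ny, nz, x, y, z, nb);
        if (count_fg_neighbors(nb) < 1) continue;  // never delete isolated
        if (!is_simple(nb)) continue;
        img[i] = 0;
        changed = true;
      }
    }
  }
  LogicalVector out(n);
  for (size_t i = 0; i < n; i++) out[i] = img[i] != 0;
  return out;
}
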