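#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

struct Nbhd {
  std::vector<int> dx, dy, dz;
};

static Nbhd make_nbhd(int connectivity) {
  Nbhd nb;
  for (int dz = -1; dz <= 1; dz++)
    for (int dy = -1; dy <= 1; dy++)
      for (int dx = -1; dx <= 1; dx++) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if ((connectivity == 6 && m > 1) || (connectivity == 18 && m > 2))
          continue;
        nb.dx.push_back(dx);
        nb.dy.push_back(dy);
        nb.dz.push_back(dz);
      }
  return nb;
}

// Connected-component labeling of a 3D (or single-slice 2D) binary mask.
// Labels are 1..k in scan order of the first voxel encountered; 0 = background.
// [[Rcpp::export]]
IntegerVector cpp_label(LogicalVector mask, IntegerVector dims, int connectivity) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  Nbhd nb = make_nbhd(connectivity);
  int nn = (int)nb.dx.size();
  IntegerVector lab(n);
  std::vector<size_t> stack;
  int next = 0;
  for (size_t i = 0; i < n; i++) {
    if (!mask[i] || lab[i] != 0) continue;
    next++;
    lab[i] = next;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      size_t cur = stack.back();
      stack.pop_back();
      int x = (int)(cur % nx);
      int y = (int)((cur / nx) % ny);
      int z = (int)(cur / ((size_t)nx * ny));
      for (int k = 0; k < nn; k++) {
        int xx = x + nb.dx[k], yy = y + nb.dy[k], zz = z + nb.dz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        size_t j = (size_t)xx + (size_t)nx * (yy + (size_t)ny * zz);
        if (mask[j] && lab[j] == 0) {
          lab[j] = next;
          stack.push_back(j);
        }
      }
    }
  }
  return lab;
}
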