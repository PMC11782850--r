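#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Quasi-Euclidean geodesic distance (voxel units) from a seed set through a
// traversable domain: Dijkstra wavefront over the 26-neighbourhood with step
// weights 1, sqrt(2), sqrt(3). Non-domain voxels get NA, unreachable domain
// voxels +Inf.
// [[Rcpp::export]]
NumericVector cpp_geodesic(LogicalVector domain, LogicalVector seeds,
                           IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<int> ddx, ddy, ddz;
  std::vector<double> w;
  for (int dz = -1; dz <= 1; dz++)
    for (int dy = -1; dy <= 1; dy++)
      for (int dx = -1; dx <= 1; dx++) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        ddx.push_back(dx);
        ddy.push_back(dy);
        ddz.push_back(dz);
        w.push_back(std::sqrt((double)(dx * dx + dy * dy + dz * dz)));
      }
  int nn = (int)ddx.size();

  NumericVector dist(n);
  typedef std::pair<double, size_t> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  for (size_t i = 0; i < n; i++) {
    if (!domain[i]) {
      dist[i] = NA_REAL;
    } else if (seeds[i]) {
      dist[i] = 0.0;
      pq.push(QE(0.0, i));
    } else {
      dist[i] = R_PosInf;
    }
  }
  while (!pq.empty()) {
    QE top = pq.top();
    pq.pop();
    double d = top.first;
    size_t cur = top.second;
    if (d > dist[cur]) continue;
    int x = (int)(cur % nx);
    int y = (int)((cur / nx) % ny);
    int z = (int)(cur / ((size_t)nx * ny));
    for (int k = 0; k < nn; k++) {
      int xx = x + ddx[k], yy = y + ddy[k], zz = z + ddz[k];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
        continue;
      size_t j = (size_t)xx + (size_t)nx * (yy + (size_t)ny * zz);
      if (ISNA(dist[j])) continue;
      double nd = d + w[k];
      if (nd < dist[j]) {
        dist[j] = nd;
        pq.push(QE(nd, j));
      }
    }
  }
  return dist;
}
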