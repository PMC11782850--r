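#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static const double DT_INF = 1e30;

// 1D squared-distance lower-envelope transform (Felzenszwalb & Huttenlocher).
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -DT_INF;
  z[1] = DT_INF;
  for (int q = 1; q < n; q++) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      k--;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = DT_INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    double dq = (double)q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

static void sqedt_inplace(std::vector<double>& g, int nx, int ny, int nz) {
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax);
  // x axis
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++) {
      size_t base = (size_t)nx * (y + (size_t)ny * z);
      for (int x = 0; x < nx; x++) f[x] = g[base + x];
      dt1d(f, d, nx);
      for (int x = 0; x < nx; x++) g[base + x] = d[x];
    }
  // y axis
  for (int z = 0; z < nz; z++)
    for (int x = 0; x < nx; x++) {
      size_t base = (size_t)x + (size_t)nx * ny * (size_t)z;
      for (int y = 0; y < ny; y++) f[y] = g[base + (size_t)nx * y];
      dt1d(f, d, ny);
      for (int y = 0; y < ny; y++) g[base + (size_t)nx * y] = d[y];
    }
  // z axis
  for (int y = 0; y < ny; y++)
    for (int x = 0; x < nx; x++) {
      size_t base = (size_t)x + (size_t)nx * y;
      size_t stride = (size_t)nx * ny;
      for (int z = 0; z < nz; z++) f[z] = g[base + stride * z];
      dt1d(f, d, nz);
      for (int z = 0; z < nz; z++) g[base + stride * z] = d[z];
    }
}

// Exact squared Euclidean distance (voxel units) from every voxel to the
// nearest TRUE voxel. Voxels with no TRUE site anywhere get a huge value.
// [[Rcpp::export]]
NumericVector cpp_sqedt(LogicalVector sites, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<double> g(n);
  for (size_t i = 0; i < n; i++) g[i] = sites[i] ? 0.0 : DT_INF;
  sqedt_inplace(g, nx, ny, nz);
  NumericVector out(n);
  for (size_t i = 0; i < n; i++) out[i] = g[i];
  return out;
}

// Morphological dilation by the discretized Euclidean ball {||x|| <= r}.
// [[Rcpp::export]]
LogicalVector cpp_ball_dilate(LogicalVector mask, IntegerVector dims, double r) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<double> g(n);
  for (size_t i = 0; i < n; i++) g[i] = mask[i] ? 0.0 : DT_INF;
  sqedt_inplace(g, nx, ny, nz);
  double r2 = r * r + 1e-6;
  LogicalVector out(n);
  for (size_t i = 0; i < n; i++) out[i] = g[i] <= r2;
  return out;
}

// Erosion by the same ball. Out-of-volume space is treated as foreground
// continuation: only observed background erodes the mask, so structures cut
// by the volume face keep their cut surface.
// [[Rcpp::export]]
LogicalVector cpp_ball_erode(LogicalVector mask, IntegerVector dims, double r) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<double> g(n);
  for (size_t i = 0; i < n; i++) g[i] = mask[i] ? DT_INF : 0.0;
  sqedt_inplace(g, nx, ny, nz);
  double r2 = r * r + 1e-6;
  LogicalVector out(n);
  for (size_t i = 0; i < n; i++) out[i] = mask[i] && !(g[i] <= r2);
  return out;
}
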