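#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Rasterize a capsule (cylinder with spherical caps, linearly tapered radius)
// into an integer label array, writing `value` wherever the current label is
// in `overwrite` (typically 0 = unassigned). Coordinates are 0-based voxel
// units. Modifies `labels` in place and returns the number of voxels set.
// [[Rcpp::export]]
int cpp_fill_capsule(IntegerVector labels, IntegerVector dims,
                     NumericVector p0, NumericVector p1, double r0, double r1,
                     int value, IntegerVector overwrite) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  double ax = p0[0], ay = p0[1], az = p0[2];
  double bx = p1[0], by = p1[1], bz = p1[2];
  double rmax = std::max(r0, r1);
  int x0 = std::max(0, (int)std::floor(std::min(ax, bx) - rmax - 1));
  int x1 = std::min(nx - 1, (int)std::ceil(std::max(ax, bx) + rmax + 1));
  int y0 = std::max(0, (int)std::floor(std::min(ay, by) - rmax - 1));
  int y1 = std::min(ny - 1, (int)std::ceil(std::max(ay, by) + rmax + 1));
  int z0 = std::max(0, (int)std::floor(std::min(az, bz) - rmax - 1));
  int z1 = std::min(nz - 1, (int)std::ceil(std::max(az, bz) + rmax + 1));
  double vx = bx - ax, vy = by - ay, vz = bz - az;
  double vv = vx * vx + vy * vy + vz * vz;
  std::vector<bool> ow(256, false);
  for (int i = 0; i < overwrite.size(); i++)
    if (overwrite[i] >= 0 && overwrite[i] < 256) ow[overwrite[i]] = true;
  int count = 0;
  for (int z = z0; z <= z1; z++)
    for (int y = y0; y <= y1; y++)
      for (int x = x0; x <= x1; x++) {
        double wx = x - ax, wy = y - ay, wz = z - az;
        double t = vv > 0 ? (wx * vx + wy * vy + wz * vz) / vv : 0.0;
        if (t < 0) t = 0;
        if (t > 1) t = 1;
        double dx = wx - t * vx, dy = wy - t * vy, dz = wz - t * vz;
        double r = r0 + t * (r1 - r0);
        if (dx * dx + dy * dy + dz * dz <= r * r + 1e-9) {
          size_t i = (size_t)x + (size_t)nx * (y + (size_t)ny * z);
          int cur = labels[i];
          if (cur == value) continue;
          if (cur >= 0 && cur < 256 && ow[cur]) {
            labels[i] = value;
            count++;
          }
        }
      }
  return count;
}

// [[Rcpp::export]]
int cpp_fill_sphere(IntegerVector labels, IntegerVector dims,
                    NumericVector center, double r, int value,
                    IntegerVector overwrite) {
  NumericVector c2 = clone(center);
  return cpp_fill_capsule(labels, dims, center, c2, r, r, value, overwrite);
}

// TRUE when every voxel within `r` of `center` currently carries a label in
// `allowed` (used for overlap-free dart throwing). Out-of-volume counts as
// not free.
// [[Rcpp::export]]
bool cpp_region_free(IntegerVector labels, IntegerVector dims,
                     NumericVector center, double r, IntegerVector allowed) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  double cx = center[0], cy = center[1], cz = center[2];
  std::vector<bool> ok(256, false);
  for (int i = 0; i < allowed.size(); i++)
    if (allowed[i] >= 0 && allowed[i] < 256) ok[allowed[i]] = true;
  int x0 = (int)std::floor(cx - r), x1 = (int)std::ceil(cx + r);
  int y0 = (int)std::floor(cy - r), y1 = (int)std::ceil(cy + r);
  int z0 = (int)std::floor(cz - r), z1 = (int)std::ceil(cz + r);
  if (x0 < 0 || y0 < 0 || z0 < 0 || x1 >= nx || y1 >= ny || z1 >= nz)
    return false;
  double r2 = r * r + 1e-9;
  for (int z = z0; z <= z1; z++)
    for (int y = y0; y <= y1; y++)
      for (int x = x0; x <= x1; x++) {
        double d2 = (x - cx) * (x - cx) + (y - cy) * (y - cy) +
                    (z - cz) * (z - cz);
        if (d2 > r2) continue;
        size_t i = (size_t)x + (size_t)nx * (y + (size_t)ny * z);
        int cur = labels[i];
        if (cur < 0 || cur >= 256 || !ok[cur]) return false;
      }
  return true;
}

// Separable Gaussian blur with reflective boundaries (sigma in voxels).
// [[Rcpp::export]]
NumericVector cpp_gauss_blur(NumericVector arr, IntegerVector dims,
                             double sigma) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  NumericVector out = clone(arr);
  if (sigma <= 0) return out;
  int rad = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> ker(2 * rad + 1);
  double s = 0;
  for (int i = -rad; i <= rad; i++) {
    ker[i + rad] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += ker[i + rad];
  }
  for (size_t i = 0; i < ker.size(); i++) ker[i] /= s;

  std::vector<double> buf(std::max(nx, std::max(ny, nz)));
  std::vector<double> res(buf.size());
  // reflect index into [0, m)
  auto refl = [](int i, int m) {
    if (m == 1) return 0;
    while (i < 0 || i >= m) {
      if (i < 0) i = -i - 1;
      if (i >= m) i = 2 * m - i - 1;
    }
    return i;
  };
  // x
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++) {
      size_t base = (size_t)nx * (y + (size_t)ny * z);
      for (int x = 0; x < nx; x++) buf[x] = out[base + x];
      for (int x = 0; x < nx; x++) {
        double a = 0;
        for (int k = -rad; k <= rad; k++) a += ker[k + rad] * buf[refl(x + k, nx)];
        res[x] = a;
      }
      for (int x = 0; x < nx; x++) out[base + x] = res[x];
    }
  // y
  for (int z = 0; z < nz; z++)
    for (int x = 0; x < nx; x++) {
      size_t base = (size_t)x + (size_t)nx * ny * (size_t)z;
      for (int y = 0; y < ny; y++) buf[y] = out[base + (size_t)nx * y];
      for (int y = 0; y < ny; y++) {
        double a = 0;
        for (int k = -rad; k <= rad; k++) a += ker[k + rad] * buf[refl(y + k, ny)];
        res[y] = a;
      }
      for (int y = 0; y < ny; y++) out[base + (size_t)nx * y] = res[y];
    }
  // z
  size_t stride = (size_t)nx * ny;
  for (int y = 0; y < ny; y++)
    for (int x = 0; x < nx; x++) {
      size_t base = (size_t)x + (size_t)nx * y;
      for (int z = 0; z < nz; z++) buf[z] = out[base + stride * z];
      for (int z = 0; z < nz; z++) {
        double a = 0;
        for (int k = -rad; k <= rad; k++) a += ker[k + rad] * buf[refl(z + k, nz)];
        res[z] = a;
      }
      for (int z = 0; z < nz; z++) out[base + stride * z] = res[z];
    }
  return out;
}
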