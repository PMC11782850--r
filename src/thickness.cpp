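#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double TH_INF = 1e30;

static void dt1d_th(const std::vector<double>& f, std::vector<double>& d,
                    int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -TH_INF;
  z[1] = TH_INF;
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
    z[k + 1] = TH_INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    double dq = (double)q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

static void sqedt_fine(std::vector<double>& g, int fx, int fy, int fz) {
  int nmax = std::max(fx, std::max(fy, fz));
  std::vector<double> f(nmax), d(nmax);
  for (int z = 0; z < fz; z++)
    for (int y = 0; y < fy; y++) {
      size_t base = (size_t)fx * (y + (size_t)fy * z);
      for (int x = 0; x < fx; x++) f[x] = g[base + x];
      dt1d_th(f, d, fx);
      for (int x = 0; x < fx; x++) g[base + x] = d[x];
    }
  for (int z = 0; z < fz; z++)
    for (int x = 0; x < fx; x++) {
      size_t base = (size_t)x + (size_t)fx * fy * (size_t)z;
      for (int y = 0; y < fy; y++) f[y] = g[base + (size_t)fx * y];
      dt1d_th(f, d, fy);
      for (int y = 0; y < fy; y++) g[base + (size_t)fx * y] = d[y];
    }
  for (int y = 0; y < fy; y++)
    for (int x = 0; x < fx; x++) {
      size_t base = (size_t)x + (size_t)fx * y;
      size_t stride = (size_t)fx * fy;
      for (int z = 0; z < fz; z++) f[z] = g[base + stride * z];
      dt1d_th(f, d, fz);
      for (int z = 0; z < fz; z++) g[base + stride * z] = d[z];
    }
}

// Local thickness by the inscribed-sphere (model-independent) definition:
// Th(x) = 2 * max{ r : x in B(c, r), B(c, r) inside the structure }.
// Sphere centers are sampled at voxel centers and at face midpoints between
// voxels. At voxel centers the radius follows the classic digital
// convention: Euclidean distance to the nearest background voxel center
// minus half a voxel (which compensates the half-voxel that center-sampled
// rasterization shaves off round objects). At face midpoints the radius is
// the exact Euclidean distance to the nearest background voxel cube --
// exact there because the nearest point of an axis-aligned cube to a
// half-lattice point is the coordinate-wise clamp, itself a half-lattice
// point. The face midpoints make structures of even voxel width (whose
// maximal sphere sits between voxel centers) exact and can never
// overestimate. Centers whose ball is contained in a neighbour's ball are
// dropped (distance ridge); remaining balls are painted taking the maximum.
// Returns thickness per voxel in voxel units; 0 on background.
// [[Rcpp::export]]
NumericVector cpp_local_thickness(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  // fine lattice: coordinates 0, 0.5, ..., nx-1 -> index f = 2*coord
  int fx = 2 * nx - 1, fy = 2 * ny - 1, fz = 2 * nz - 1;
  size_t fn = (size_t)fx * fy * fz;
  std::vector<float> R(fn, 0.0f);
  std::vector<double> g(fn);

  // pass 1: EDT to background voxel centers -> radii at voxel centers
  std::fill(g.begin(), g.end(), TH_INF);
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++) {
        size_t i = (size_t)x + (size_t)nx * (y + (size_t)ny * z);
        if (!mask[i])
          g[(size_t)(2 * x) + (size_t)fx * ((2 * y) + (size_t)fy * (2 * z))] =
              0.0;
      }
  sqedt_fine(g, fx, fy, fz);
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++) {
        size_t fi =
            (size_t)(2 * x) + (size_t)fx * ((2 * y) + (size_t)fy * (2 * z));
        double r = (g[fi] >= TH_INF) ? 0.0 : std::sqrt(g[fi]) / 2.0 - 0.5;
        if (r > 0) R[fi] = (float)r;
      }

  // pass 2: EDT to the background cube surface -> radii at face midpoints
  std::fill(g.begin(), g.end(), TH_INF);
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++) {
        size_t i = (size_t)x + (size_t)nx * (y + (size_t)ny * z);
        if (mask[i]) continue;
        for (int dz = -1; dz <= 1; dz++)
          for (int dy = -1; dy <= 1; dy++)
            for (int dx = -1; dx <= 1; dx++) {
              int px = 2 * x + dx, py = 2 * y + dy, pz = 2 * z + dz;
              if (px < 0 || px >= fx || py < 0 || py >= fy || pz < 0 ||
                  pz >= fz)
                continue;
              g[(size_t)px + (size_t)fx * (py + (size_t)fy * pz)] = 0.0;
            }
      }
  sqedt_fine(g, fx, fy, fz);
  {
    size_t i = 0;
    for (int pz = 0; pz < fz; pz++)
      for (int py = 0; py < fy; py++)
        for (int px = 0; px < fx; px++, i++) {
          if (((px & 1) + (py & 1) + (pz & 1)) != 1) continue;
          double r = (g[i] >= TH_INF) ? 0.0 : std::sqrt(g[i]) / 2.0;
          if (r > 0 && r > R[i]) R[i] = (float)r;
        }
  }
  std::vector<double>().swap(g);  // release

  NumericVector out(n);  // zero-initialized
  for (int pz = 0; pz < fz; pz++)
    for (int py = 0; py < fy; py++)
      for (int px = 0; px < fx; px++) {
        size_t pi = (size_t)px + (size_t)fx * (py + (size_t)fy * pz);
        double r = R[pi];
        if (r <= 0) continue;
        // ridge test: drop if a fine neighbour's ball contains this ball
        bool dominated = false;
        for (int dz = -1; dz <= 1 && !dominated; dz++)
          for (int dy = -1; dy <= 1 && !dominated; dy++)
            for (int dx = -1; dx <= 1 && !dominated; dx++) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              int qx = px + dx, qy = py + dy, qz = pz + dz;
              if (qx < 0 || qx >= fx || qy < 0 || qy >= fy || qz < 0 ||
                  qz >= fz)
                continue;
              double step =
                  0.5 * std::sqrt((double)(dx * dx + dy * dy + dz * dz));
              size_t qi = (size_t)qx + (size_t)fx * (qy + (size_t)fy * qz);
              if (R[qi] >= r + step - 1e-9) dominated = true;
            }
        if (dominated) continue;
        // paint the ball (coarse voxels within r of center (px,py,pz)/2)
        double cx = px / 2.0, cy = py / 2.0, cz = pz / 2.0;
        double rr = r + 1e-6;
        int x0 = (int)std::ceil(cx - rr), x1 = (int)std::floor(cx + rr);
        int y0 = (int)std::ceil(cy - rr), y1 = (int)std::floor(cy + rr);
        int z0 = (int)std::ceil(cz - rr), z1 = (int)std::floor(cz + rr);
        if (x0 < 0) x0 = 0;
        if (y0 < 0) y0 = 0;
        if (z0 < 0) z0 = 0;
        if (x1 >= nx) x1 = nx - 1;
        if (y1 >= ny) y1 = ny - 1;
        if (z1 >= nz) z1 = nz - 1;
        double th = 2.0 * r;
        double rr2 = rr * rr;
        for (int z = z0; z <= z1; z++)
          for (int y = y0; y <= y1; y++) {
            double dz2 = (z - cz) * (z - cz) + (y - cy) * (y - cy);
            if (dz2 > rr2) continue;
            size_t base = (size_t)nx * (y + (size_t)ny * z);
            for (int x = x0; x <= x1; x++) {
              double d2 = dz2 + (x - cx) * (x - cx);
              size_t vi = base + x;
              if (d2 <= rr2 && mask[vi] && out[vi] < th) out[vi] = th;
            }
          }
      }
  return out;
}
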