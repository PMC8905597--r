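#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// 3D connected-component labelling on a logical grid.
// connectivity: 6 (faces), 18 (faces+edges) or 26 (faces+edges+corners).
// Returns integer labels (0 = background), components numbered from 1 in
// first-encountered order (column-major scan), so labelling is deterministic.
// [[Rcpp::export]]
IntegerVector cc_label_cpp(LogicalVector mask, IntegerVector dims, int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");

  // neighbour offsets
  std::vector<int> dx, dy, dz;
  for (int cz = -1; cz <= 1; ++cz)
    for (int cy = -1; cy <= 1; ++cy)
      for (int cx = -1; cx <= 1; ++cx) {
        int nn = std::abs(cx) + std::abs(cy) + std::abs(cz);
        if (nn == 0) continue;
        if (connectivity == 6 && nn > 1) continue;
        if (connectivity == 18 && nn > 2) continue;
        dx.push_back(cx); dy.push_back(cy); dz.push_back(cz);
      }

  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int cur = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++cur;
    lab[i] = cur;
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      int x = (int)(v % nx);
      int y = (int)((v / nx) % ny);
      int z = (int)(v / ((R_xlen_t)nx * ny));
      for (size_t k = 0; k < dx.size(); ++k) {
        int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
        R_xlen_t w = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
        if (mask[w] && lab[w] == 0) { lab[w] = cur; stack.push_back(w); }
      }
    }
  }
  return lab;
}

// 1D squared-distance transform (Felzenszwalb & Huttenlocher), sample step s.
static void dt1d(std::vector<double>& f, double s2, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& zb) {
  const int n = (int)f.size();
  int k = 0;
  v[0] = 0;
  zb[0] = -std::numeric_limits<double>::infinity();
  zb[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    if (f[q] == std::numeric_limits<double>::infinity() &&
        f[v[k]] == std::numeric_limits<double>::infinity()) {
      // both unreachable: parabola comparison is ill-defined; skip candidate
      continue;
    }
    double sden = 2.0 * s2 * (q - v[k]);
    double sval = ((f[q] + s2 * q * q) - (f[v[k]] + s2 * (double)v[k] * v[k])) / sden;
    while (k > 0 && sval <= zb[k]) {
      --k;
      sden = 2.0 * s2 * (q - v[k]);
      sval = ((f[q] + s2 * q * q) - (f[v[k]] + s2 * (double)v[k] * v[k])) / sden;
    }
    ++k;
    v[k] = q;
    zb[k] = sval;
    zb[k + 1] = std::numeric_limits<double>::infinity();
  }
  int kk = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[kk + 1] < q) ++kk;
    double dq = (double)(q - v[kk]);
    d[q] = s2 * dq * dq + f[v[kk]];
  }
  for (int q = 0; q < n; ++q) f[q] = d[q];
}

// Exact squared Euclidean distance (mm^2) from every voxel to the nearest
// seed voxel, with anisotropic spacing. Voxels with no seed anywhere get Inf.
// [[Rcpp::export]]
NumericVector edt_sq_cpp(LogicalVector seed, IntegerVector dims, NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (seed.size() != n) stop("seed length does not match dims");
  const double INF = std::numeric_limits<double>::infinity();

  NumericVector g(n);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = seed[i] ? 0.0 : INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), zb(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  double s2 = spacing[0] * spacing[0];
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
      f.assign(g.begin() + base, g.begin() + base + nx);
      f.resize(nx);
      dt1d(f, s2, d, v, zb);
      for (int x = 0; x < nx; ++x) g[base + x] = f[x];
    }
  // pass along y
  s2 = spacing[1] * spacing[1];
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      f.resize(ny);
      for (int y = 0; y < ny; ++y) f[y] = g[(R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x];
      dt1d(f, s2, d, v, zb);
      for (int y = 0; y < ny; ++y) g[(R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x] = f[y];
    }
  // pass along z
  s2 = spacing[2] * spacing[2];
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      f.resize(nz);
      for (int z = 0; z < nz; ++z) f[z] = g[(R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x];
      dt1d(f, s2, d, v, zb);
      for (int z = 0; z < nz; ++z) g[(R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x] = f[z];
    }
  return g;
}
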