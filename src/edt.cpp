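#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static const double DT_INF = 1e30;

// 1D lower-envelope squared distance transform (Felzenszwalb & Huttenlocher)
// with propagation of the source (feature) index.
static void dt1d(int n, const double* f, const int* srcin,
                 double* d, int* srcout, int* v, double* z) {
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (f[q] >= DT_INF) continue;
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -DT_INF; z[1] = DT_INF;
      continue;
    }
    double s = 0.0;
    while (k >= 0) {
      int p = v[k];
      s = ((f[q] + (double)q * q) - (f[p] + (double)p * p)) / (2.0 * (q - p));
      if (s <= z[k]) --k; else break;
    }
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -DT_INF; z[1] = DT_INF;
    } else {
      ++k; v[k] = q; z[k] = s; z[k + 1] = DT_INF;
    }
  }
  if (k < 0) {
    for (int q = 0; q < n; ++q) { d[q] = DT_INF; srcout[q] = -1; }
    return;
  }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    while (z[j + 1] < q) ++j;
    int p = v[j];
    double dq = (double)(q - p) * (q - p) + f[p];
    d[q] = dq;
    srcout[q] = srcin[p];
  }
}

// Squared Euclidean distance to the nearest feature voxel, exact, with the
// linear index (1-based) of that nearest feature voxel.
// [[Rcpp::export]]
List edt_cpp(LogicalVector feature, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector d(n);
  IntegerVector src(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (feature[i]) { d[i] = 0.0; src[i] = (int)i; }
    else { d[i] = DT_INF; src[i] = -1; }
  }
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), dd(nmax), z(nmax + 1);
  std::vector<int> si(nmax), so(nmax), v(nmax);

  // pass along x
  for (int zz = 0; zz < nz; ++zz)
    for (int yy = 0; yy < ny; ++yy) {
      R_xlen_t base = (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
      for (int xx = 0; xx < nx; ++xx) { f[xx] = d[base + xx]; si[xx] = src[base + xx]; }
      dt1d(nx, f.data(), si.data(), dd.data(), so.data(), v.data(), z.data());
      for (int xx = 0; xx < nx; ++xx) { d[base + xx] = dd[xx]; src[base + xx] = so[xx]; }
    }
  // pass along y
  for (int zz = 0; zz < nz; ++zz)
    for (int xx = 0; xx < nx; ++xx) {
      R_xlen_t base = xx + (R_xlen_t)nx * ny * zz;
      for (int yy = 0; yy < ny; ++yy) { f[yy] = d[base + (R_xlen_t)nx * yy]; si[yy] = src[base + (R_xlen_t)nx * yy]; }
      dt1d(ny, f.data(), si.data(), dd.data(), so.data(), v.data(), z.data());
      for (int yy = 0; yy < ny; ++yy) { d[base + (R_xlen_t)nx * yy] = dd[yy]; src[base + (R_xlen_t)nx * yy] = so[yy]; }
    }
  // pass along z
  R_xlen_t nxny = (R_xlen_t)nx * ny;
  for (int yy = 0; yy < ny; ++yy)
    for (int xx = 0; xx < nx; ++xx) {
      R_xlen_t base = xx + (R_xlen_t)nx * yy;
      for (int zz = 0; zz < nz; ++zz) { f[zz] = d[base + nxny * zz]; si[zz] = src[base + nxny * zz]; }
      dt1d(nz, f.data(), si.data(), dd.data(), so.data(), v.data(), z.data());
      for (int zz = 0; zz < nz; ++zz) { d[base + nxny * zz] = dd[zz]; src[base + nxny * zz] = so[zz]; }
    }

  IntegerVector src1(n);
  for (R_xlen_t i = 0; i < n; ++i) src1[i] = src[i] < 0 ? NA_INTEGER : src[i] + 1;
  return List::create(_["dist2"] = d, _["nearest"] = src1);
}

// City-block (L1) distance to the nearest background voxel; voxels outside
// the grid count as background. Inside the mask this equals the number of
// 6-connected (cross) erosion steps a voxel survives plus one.
// [[Rcpp::export]]
IntegerVector l1_depth_cpp(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nxny = (R_xlen_t)nx * ny;
  const R_xlen_t n = nxny * nz;
  const int BIG = nx + ny + nz + 3;
  IntegerVector d(n);
  // forward
  for (int zz = 0; zz < nz; ++zz)
    for (int yy = 0; yy < ny; ++yy)
      for (int xx = 0; xx < nx; ++xx) {
        R_xlen_t i = xx + (R_xlen_t)nx * yy + nxny * zz;
        if (!mask[i]) { d[i] = 0; continue; }
        int best = BIG;
        int cx = (xx > 0) ? d[i - 1] + 1 : 1;
        int cy = (yy > 0) ? d[i - nx] + 1 : 1;
        int cz = (zz > 0) ? d[i - nxny] + 1 : 1;
        best = std::min(best, std::min(cx, std::min(cy, cz)));
        d[i] = best;
      }
  // backward
  for (int zz = nz - 1; zz >= 0; --zz)
    for (int yy = ny - 1; yy >= 0; --yy)
      for (int xx = nx - 1; xx >= 0; --xx) {
        R_xlen_t i = xx + (R_xlen_t)nx * yy + nxny * zz;
        if (!mask[i]) continue;
        int best = d[i];
        int cx = (xx < nx - 1) ? d[i + 1] + 1 : 1;
        int cy = (yy < ny - 1) ? d[i + nx] + 1 : 1;
        int cz = (zz < nz - 1) ? d[i + nxny] + 1 : 1;
        best = std::min(best, std::min(cx, std::min(cy, cz)));
        d[i] = best;
      }
  return d;
}
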