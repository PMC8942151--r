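#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Separable Gaussian smoothing of a 3D volume, reflected boundaries.
// [[Rcpp::export]]
NumericVector gauss3_cpp(NumericVector vol, IntegerVector dims, double sigma) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nxny = (R_xlen_t)nx * ny;
  const R_xlen_t n = nxny * nz;
  int rad = (int)std::ceil(3.0 * sigma);
  if (rad < 1) rad = 1;
  std::vector<double> ker(2 * rad + 1);
  double s = 0.0;
  for (int k = -rad; k <= rad; ++k) {
    ker[k + rad] = std::exp(-0.5 * k * k / (sigma * sigma));
    s += ker[k + rad];
  }
  for (double& v : ker) v /= s;

  NumericVector a = clone(vol);
  NumericVector b(n);

  auto reflect = [](int i, int n) {
    while (i < 0 || i >= n) {
      if (i < 0) i = -i - 1;
      if (i >= n) i = 2 * n - i - 1;
    }
    return i;
  };

  // x pass
  for (int zz = 0; zz < nz; ++zz)
    for (int yy = 0; yy < ny; ++yy) {
      R_xlen_t base = (R_xlen_t)nx * yy + nxny * zz;
      for (int xx = 0; xx < nx; ++xx) {
        double acc = 0.0;
        for (int k = -rad; k <= rad; ++k)
          acc += ker[k + rad] * a[base + reflect(xx + k, nx)];
        b[base + xx] = acc;
      }
    }
  // y pass
  for (int zz = 0; zz < nz; ++zz)
    for (int xx = 0; xx < nx; ++xx) {
      R_xlen_t base = xx + nxny * zz;
      for (int yy = 0; yy < ny; ++yy) {
        double acc = 0.0;
        for (int k = -rad; k <= rad; ++k)
          acc += ker[k + rad] * b[base + (R_xlen_t)nx * reflect(yy + k, ny)];
        a[base + (R_xlen_t)nx * yy] = acc;
      }
    }
  // z pass
  for (int yy = 0; yy < ny; ++yy)
    for (int xx = 0; xx < nx; ++xx) {
      R_xlen_t base = xx + (R_xlen_t)nx * yy;
      for (int zz = 0; zz < nz; ++zz) {
        double acc = 0.0;
        for (int k = -rad; k <= rad; ++k)
          acc += ker[k + rad] * a[base + nxny * reflect(zz + k, nz)];
        b[base + nxny * zz] = acc;
      }
    }
  return b;
}
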