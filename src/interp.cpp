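#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Trilinear sampling of a scalar volume at continuous 1-based coordinates,
// clamped to the grid.
static inline double tri_sample(const double* v, int nx, int ny, int nz,
                                double x, double y, double z) {
  // convert to 0-based
  x -= 1.0; y -= 1.0; z -= 1.0;
  if (x < 0) x = 0; if (x > nx - 1) x = nx - 1;
  if (y < 0) y = 0; if (y > ny - 1) y = ny - 1;
  if (z < 0) z = 0; if (z > nz - 1) z = nz - 1;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  if (x0 > nx - 2) x0 = nx - 2; if (x0 < 0) x0 = 0;
  if (y0 > ny - 2) y0 = ny - 2; if (y0 < 0) y0 = 0;
  if (z0 > nz - 2) z0 = nz - 2; if (z0 < 0) z0 = 0;
  double fx = x - x0, fy = y - y0, fz = z - z0;
  R_xlen_t nxny = (R_xlen_t)nx * ny;
  R_xlen_t i000 = x0 + (R_xlen_t)nx * y0 + nxny * z0;
  double c00 = v[i000] * (1 - fx) + v[i000 + 1] * fx;
  double c10 = v[i000 + nx] * (1 - fx) + v[i000 + nx + 1] * fx;
  double c01 = v[i000 + nxny] * (1 - fx) + v[i000 + nxny + 1] * fx;
  double c11 = v[i000 + nxny + nx] * (1 - fx) + v[i000 + nxny + nx + 1] * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// [[Rcpp::export]]
NumericVector trilinear_cpp(NumericVector vol, IntegerVector dims, NumericMatrix pts) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int np = pts.nrow();
  NumericVector out(np);
  const double* v = vol.begin();
  for (int i = 0; i < np; ++i)
    out[i] = tri_sample(v, nx, ny, nz, pts(i, 0), pts(i, 1), pts(i, 2));
  return out;
}

// Sample a 3-component field (array nx x ny x nz x 3) at continuous 1-based
// points; returns np x 3 plus an out-of-domain flag per point.
// [[Rcpp::export]]
List field_at_points_cpp(NumericVector field, IntegerVector dims, NumericMatrix pts) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t ncomp_stride = (R_xlen_t)nx * ny * nz;
  const int np = pts.nrow();
  NumericMatrix out(np, 3);
  LogicalVector oob(np);
  const double* v = field.begin();
  for (int i = 0; i < np; ++i) {
    double x = pts(i, 0), y = pts(i, 1), z = pts(i, 2);
    oob[i] = (x < 1 || x > nx || y < 1 || y > ny || z < 1 || z > nz);
    for (int c = 0; c < 3; ++c)
      out(i, c) = tri_sample(v + ncomp_stride * c, nx, ny, nz, x, y, z);
  }
  return List::create(_["values"] = out, _["oob"] = oob);
}

// Warp a scalar volume by a dense displacement field: out(x) = vol(x + u(x)),
// trilinear with clamping; also flags voxels whose source fell outside.
// [[Rcpp::export]]
List warp_volume_cpp(NumericVector vol, NumericVector field, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericVector out(nvox);
  LogicalVector oob(nvox);
  const double* v = vol.begin();
  const double* ux = field.begin();
  const double* uy = ux + nvox;
  const double* uz = uy + nvox;
  R_xlen_t i = 0;
  for (int zz = 1; zz <= nz; ++zz)
    for (int yy = 1; yy <= ny; ++yy)
      for (int xx = 1; xx <= nx; ++xx, ++i) {
        double px = xx + ux[i], py = yy + uy[i], pz = zz + uz[i];
        oob[i] = (px < 1 || px > nx || py < 1 || py > ny || pz < 1 || pz > nz);
        out[i] = tri_sample(v, nx, ny, nz, px, py, pz);
      }
  return List::create(_["warped"] = out, _["oob"] = oob);
}

// Nearest-neighbour warp for label volumes: out(x) = lab(round(x + u(x))).
// [[Rcpp::export]]
IntegerVector warp_labels_nn_cpp(IntegerVector lab, NumericVector field, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  IntegerVector out(nvox);
  const double* ux = field.begin();
  const double* uy = ux + nvox;
  const double* uz = uy + nvox;
  R_xlen_t i = 0;
  for (int zz = 1; zz <= nz; ++zz)
    for (int yy = 1; yy <= ny; ++yy)
      for (int xx = 1; xx <= nx; ++xx, ++i) {
        int px = (int)std::lround(xx + ux[i]);
        int py = (int)std::lround(yy + uy[i]);
        int pz = (int)std::lround(zz + uz[i]);
        if (px < 1) px = 1; if (px > nx) px = nx;
        if (py < 1) py = 1; if (py > ny) py = ny;
        if (pz < 1) pz = 1; if (pz > nz) pz = nz;
        out[i] = lab[(px - 1) + (R_xlen_t)nx * (py - 1) + (R_xlen_t)nx * ny * (pz - 1)];
      }
  return out;
}
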