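#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Cubic B-spline free-form deformation. A displacement component at voxel
// x (0-based) is sum_j c[i+j] * b_j(t) with g = x / spacing, i = floor(g),
// t = g - i, over the four basis functions; control point c (0-based index k)
// sits at physical position (k - 1) * spacing, so i maps to coefficients
// k = i .. i+3. Number of control points per axis must be
// floor((dim-1)/spacing) + 4.

static inline void bs_weights(double t, double w[4]) {
  double t2 = t * t, t3 = t2 * t;
  w[0] = (1 - 3 * t + 3 * t2 - t3) / 6.0;
  w[1] = (4 - 6 * t2 + 3 * t3) / 6.0;
  w[2] = (1 + 3 * t + 3 * t2 - 3 * t3) / 6.0;
  w[3] = t3 / 6.0;
}

struct AxisTab {
  std::vector<int> i0;       // first coefficient index per voxel
  std::vector<double> w;     // 4 weights per voxel
};

static AxisTab axis_table(int n, double spacing) {
  AxisTab tab;
  tab.i0.resize(n);
  tab.w.resize(4 * (size_t)n);
  for (int x = 0; x < n; ++x) {
    double g = x / spacing;
    int i = (int)std::floor(g);
    double t = g - i;
    tab.i0[x] = i;
    bs_weights(t, &tab.w[4 * (size_t)x]);
  }
  return tab;
}

// Dense 3-component displacement field from a coefficient grid
// (dims ncx x ncy x ncz x 3) on a voxel grid dims nx x ny x nz.
// [[Rcpp::export]]
NumericVector bs_dense_cpp(NumericVector coef, IntegerVector ncdims,
                           double spacing, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ncx = ncdims[0], ncy = ncdims[1], ncz = ncdims[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  const R_xlen_t ncvox = (R_xlen_t)ncx * ncy * ncz;
  NumericVector out(nvox * 3);
  AxisTab tx = axis_table(nx, spacing), ty = axis_table(ny, spacing), tz = axis_table(nz, spacing);
  const double* c = coef.begin();
  double* o = out.begin();
  R_xlen_t i = 0;
  for (int zz = 0; zz < nz; ++zz) {
    const double* wz = &tz.w[4 * (size_t)zz];
    int z0 = tz.i0[zz];
    for (int yy = 0; yy < ny; ++yy) {
      const double* wy = &ty.w[4 * (size_t)yy];
      int y0 = ty.i0[yy];
      for (int xx = 0; xx < nx; ++xx, ++i) {
        const double* wx = &tx.w[4 * (size_t)xx];
        int x0 = tx.i0[xx];
        double acc[3] = {0, 0, 0};
        for (int c3 = 0; c3 < 4; ++c3) {
          double wzz = wz[c3];
          R_xlen_t zoff = (R_xlen_t)ncx * ncy * (z0 + c3);
          for (int c2 = 0; c2 < 4; ++c2) {
            double wyz = wy[c2] * wzz;
            R_xlen_t yoff = zoff + (R_xlen_t)ncx * (y0 + c2);
            for (int c1 = 0; c1 < 4; ++c1) {
              double w = wx[c1] * wyz;
              R_xlen_t ci = yoff + (x0 + c1);
              acc[0] += w * c[ci];
              acc[1] += w * c[ci + ncvox];
              acc[2] += w * c[ci + 2 * ncvox];
            }
          }
        }
        o[i] = acc[0];
        o[i + nvox] = acc[1];
        o[i + 2 * nvox] = acc[2];
      }
    }
  }
  return out;
}

static inline double tri(const double* v, int nx, int ny, int nz,
                         double x, double y, double z) {
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

// Mean SSD between fixed and moving warped by the B-spline field, with the
// gradient with respect to the coefficients (chain rule: residual times the
// warped moving-image gradient splatted onto the control grid).
// gx, gy, gz: central-difference gradient volumes of the moving image.
// [[Rcpp::export]]
List bs_ssd_cpp(NumericVector fixedv, NumericVector movingv,
                NumericVector gx, NumericVector gy, NumericVector gz,
                IntegerVector dims, NumericVector coef, IntegerVector ncdims,
                double spacing, bool want_grad) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ncx = ncdims[0], ncy = ncdims[1], ncz = ncdims[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  const R_xlen_t ncvox = (R_xlen_t)ncx * ncy * ncz;
  AxisTab tx = axis_table(nx, spacing), ty = axis_table(ny, spacing), tz = axis_table(nz, spacing);
  const double* c = coef.begin();
  const double* F = fixedv.begin();
  const double* M = movingv.begin();
  const double* GX = gx.begin();
  const double* GY = gy.begin();
  const double* GZ = gz.begin();
  NumericVector grad(want_grad ? ncvox * 3 : 1);
  double* G = grad.begin();
  double E = 0.0;
  R_xlen_t i = 0;
  for (int zz = 0; zz < nz; ++zz) {
    const double* wz = &tz.w[4 * (size_t)zz];
    int z0 = tz.i0[zz];
    for (int yy = 0; yy < ny; ++yy) {
      const double* wy = &ty.w[4 * (size_t)yy];
      int y0 = ty.i0[yy];
      for (int xx = 0; xx < nx; ++xx, ++i) {
        const double* wx = &tx.w[4 * (size_t)xx];
        int x0 = tx.i0[xx];
        double u0 = 0, u1 = 0, u2 = 0;
        for (int c3 = 0; c3 < 4; ++c3) {
          R_xlen_t zoff = (R_xlen_t)ncx * ncy * (z0 + c3);
          for (int c2 = 0; c2 < 4; ++c2) {
            R_xlen_t yoff = zoff + (R_xlen_t)ncx * (y0 + c2);
            double wyz = wy[c2] * wz[c3];
            for (int c1 = 0; c1 < 4; ++c1) {
              double w = wx[c1] * wyz;
              R_xlen_t ci = yoff + (x0 + c1);
              u0 += w * c[ci];
              u1 += w * c[ci + ncvox];
              u2 += w * c[ci + 2 * ncvox];
            }
          }
        }
        double px = xx + u0, py = yy + u1, pz = zz + u2;
        double m = tri(M, nx, ny, nz, px, py, pz);
        double r = m - F[i];
        E += r * r;
        if (want_grad && r != 0.0) {
          double dgx = tri(GX, nx, ny, nz, px, py, pz);
          double dgy = tri(GY, nx, ny, nz, px, py, pz);
          double dgz = tri(GZ, nx, ny, nz, px, py, pz);
          double f0 = 2.0 * r * dgx, f1 = 2.0 * r * dgy, f2 = 2.0 * r * dgz;
          for (int c3 = 0; c3 < 4; ++c3) {
            R_xlen_t zoff = (R_xlen_t)ncx * ncy * (z0 + c3);
            for (int c2 = 0; c2 < 4; ++c2) {
              R_xlen_t yoff = zoff + (R_xlen_t)ncx * (y0 + c2);
              double wyz = wy[c2] * wz[c3];
              for (int c1 = 0; c1 < 4; ++c1) {
                double w = wx[c1] * wyz;
                R_xlen_t ci = yoff + (x0 + c1);
                G[ci] += f0 * w;
                G[ci + ncvox] += f1 * w;
                G[ci + 2 * ncvox] += f2 * w;
              }
            }
          }
        }
      }
    }
  }
  E /= (double)nvox;
  if (want_grad) for (R_xlen_t k = 0; k < ncvox * 3; ++k) G[k] /= (double)nvox;
  return List::create(_["value"] = E, _["grad"] = grad);
}
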