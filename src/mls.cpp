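#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Moving-least-squares corrected kernel divergence of a displacement field,
// restricted to the segmented voxel set Omega. For each voxel i in Omega the
// uncorrected kernel gradient sums over Omega neighbours j are assembled into
//   P = sum_j gradW(x_j - x_i) (x) (x_j - x_i)   (3x3)
//   b_k = sum_j (u_k(x_j) - u_k(x_i)) gradW(x_j - x_i)
// and the corrected divergence is sum_k (P^{-1} b_k)_k, which is exact for
// affine fields wherever P is invertible (linear consistency). Voxels with an
// ill-conditioned P are flagged invalid.
// offs: m x 3 integer offsets, gw: m x 3 kernel gradient at each offset.
// [[Rcpp::export]]
List mls_div_cpp(NumericVector field, LogicalVector omega, IntegerVector dims,
                 IntegerMatrix offs, NumericMatrix gw, double cond_max) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nxny = (R_xlen_t)nx * ny;
  const R_xlen_t nvox = nxny * nz;
  const int m = offs.nrow();
  const double* ux = field.begin();
  const double* uy = ux + nvox;
  const double* uz = uy + nvox;
  NumericVector div(nvox);
  LogicalVector valid(nvox);

  std::vector<int> ox(m), oy(m), oz(m);
  std::vector<double> g0(m), g1(m), g2(m);
  for (int k = 0; k < m; ++k) {
    ox[k] = offs(k, 0); oy[k] = offs(k, 1); oz[k] = offs(k, 2);
    g0[k] = gw(k, 0); g1[k] = gw(k, 1); g2[k] = gw(k, 2);
  }

  R_xlen_t i = 0;
  for (int zz = 0; zz < nz; ++zz)
    for (int yy = 0; yy < ny; ++yy)
      for (int xx = 0; xx < nx; ++xx, ++i) {
        if (!omega[i]) continue;
        double P[3][3] = {{0,0,0},{0,0,0},{0,0,0}};
        double B[3][3] = {{0,0,0},{0,0,0},{0,0,0}}; // B[k][l] = sum du_k gw_l
        double u0 = ux[i], v0 = uy[i], w0 = uz[i];
        for (int k = 0; k < m; ++k) {
          int x2 = xx + ox[k], y2 = yy + oy[k], z2 = zz + oz[k];
          if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz) continue;
          R_xlen_t j = x2 + (R_xlen_t)nx * y2 + nxny * z2;
          if (!omega[j]) continue;
          double gwk0 = g0[k], gwk1 = g1[k], gwk2 = g2[k];
          // P_lm += gw_l * dx_m
          P[0][0] += gwk0 * ox[k]; P[0][1] += gwk0 * oy[k]; P[0][2] += gwk0 * oz[k];
          P[1][0] += gwk1 * ox[k]; P[1][1] += gwk1 * oy[k]; P[1][2] += gwk1 * oz[k];
          P[2][0] += gwk2 * ox[k]; P[2][1] += gwk2 * oy[k]; P[2][2] += gwk2 * oz[k];
          double d0 = ux[j] - u0, d1 = uy[j] - v0, d2 = uz[j] - w0;
          B[0][0] += d0 * gwk0; B[0][1] += d0 * gwk1; B[0][2] += d0 * gwk2;
          B[1][0] += d1 * gwk0; B[1][1] += d1 * gwk1; B[1][2] += d1 * gwk2;
          B[2][0] += d2 * gwk0; B[2][1] += d2 * gwk1; B[2][2] += d2 * gwk2;
        }
        // invert P by adjugate
        double det =
          P[0][0] * (P[1][1] * P[2][2] - P[1][2] * P[2][1]) -
          P[0][1] * (P[1][0] * P[2][2] - P[1][2] * P[2][0]) +
          P[0][2] * (P[1][0] * P[2][1] - P[1][1] * P[2][0]);
        double n1 = 0.0;
        for (int a = 0; a < 3; ++a)
          for (int b = 0; b < 3; ++b) n1 = std::max(n1, std::fabs(P[a][b]));
        if (std::fabs(det) < 1e-12 * std::max(1.0, n1 * n1 * n1)) { valid[i] = FALSE; continue; }
        double L[3][3];
        L[0][0] =  (P[1][1] * P[2][2] - P[1][2] * P[2][1]) / det;
        L[0][1] = -(P[0][1] * P[2][2] - P[0][2] * P[2][1]) / det;
        L[0][2] =  (P[0][1] * P[1][2] - P[0][2] * P[1][1]) / det;
        L[1][0] = -(P[1][0] * P[2][2] - P[1][2] * P[2][0]) / det;
        L[1][1] =  (P[0][0] * P[2][2] - P[0][2] * P[2][0]) / det;
        L[1][2] = -(P[0][0] * P[1][2] - P[0][2] * P[1][0]) / det;
        L[2][0] =  (P[1][0] * P[2][1] - P[1][1] * P[2][0]) / det;
        L[2][1] = -(P[0][0] * P[2][1] - P[0][1] * P[2][0]) / det;
        L[2][2] =  (P[0][0] * P[1][1] - P[0][1] * P[1][0]) / det;
        double n2 = 0.0;
        for (int a = 0; a < 3; ++a)
          for (int b = 0; b < 3; ++b) n2 = std::max(n2, std::fabs(L[a][b]));
        if (n1 * n2 > cond_max) { valid[i] = FALSE; continue; }
        // div = sum_k sum_l L[k][l] * B[k][l]  (gradient estimate of u_k is L b_k)
        double dv = 0.0;
        for (int k = 0; k < 3; ++k)
          for (int l = 0; l < 3; ++l) dv += L[k][l] * B[k][l];
        div[i] = dv;
        valid[i] = TRUE;
      }
  return List::create(_["div"] = div, _["valid"] = valid);
}
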