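#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// 6-connected (face-neighbour cross) erosion; outside the grid is background.
// [[Rcpp::export]]
LogicalVector erode6_cpp(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nxny = (R_xlen_t)nx * ny;
  LogicalVector out((R_xlen_t)nxny * nz);
  for (int zz = 0; zz < nz; ++zz)
    for (int yy = 0; yy < ny; ++yy)
      for (int xx = 0; xx < nx; ++xx) {
        R_xlen_t i = xx + (R_xlen_t)nx * yy + nxny * zz;
        if (!mask[i]) { out[i] = FALSE; continue; }
        bool keep =
          xx > 0 && mask[i - 1] && xx < nx - 1 && mask[i + 1] &&
          yy > 0 && mask[i - nx] && yy < ny - 1 && mask[i + nx] &&
          zz > 0 && mask[i - nxny] && zz < nz - 1 && mask[i + nxny];
        out[i] = keep;
      }
  return out;
}

// 6-connected dilation.
// [[Rcpp::export]]
LogicalVector dilate6_cpp(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nxny = (R_xlen_t)nx * ny;
  LogicalVector out((R_xlen_t)nxny * nz);
  for (int zz = 0; zz < nz; ++zz)
    for (int yy = 0; yy < ny; ++yy)
      for (int xx = 0; xx < nx; ++xx) {
        R_xlen_t i = xx + (R_xlen_t)nx * yy + nxny * zz;
        bool on = mask[i] ||
          (xx > 0 && mask[i - 1]) || (xx < nx - 1 && mask[i + 1]) ||
          (yy > 0 && mask[i - nx]) || (yy < ny - 1 && mask[i + nx]) ||
          (zz > 0 && mask[i - nxny]) || (zz < nz - 1 && mask[i + nxny]);
        out[i] = on;
      }
  return out;
}

// Connected-component labelling (connectivity 6 or 26), BFS, labels 1..k.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims, int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nxny = (R_xlen_t)nx * ny;
  const R_xlen_t n = nxny * nz;
  IntegerVector lab(n);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t seed = 0; seed < n; ++seed) {
    if (!mask[seed] || lab[seed]) continue;
    ++next;
    lab[seed] = next;
    stack.push_back(seed);
    while (!stack.empty()) {
      R_xlen_t i = stack.back(); stack.pop_back();
      int xx = (int)(i % nx), yy = (int)((i / nx) % ny), zz = (int)(i / nxny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            int ad = std::abs(dx) + std::abs(dy) + std::abs(dz);
            if (ad == 0) continue;
            if (connectivity == 6 && ad != 1) continue;
            int x2 = xx + dx, y2 = yy + dy, z2 = zz + dz;
            if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz) continue;
            R_xlen_t j = x2 + (R_xlen_t)nx * y2 + nxny * z2;
            if (mask[j] && !lab[j]) { lab[j] = next; stack.push_back(j); }
          }
    }
  }
  lab.attr("n") = next;
  return lab;
}

// Geodesic dilation: grow seed within mask by BFS (6-connectivity), up to
// `steps` layers; steps < 0 means reconstruction (grow until stable).
// [[Rcpp::export]]
LogicalVector geodesic_dilate_cpp(LogicalVector seed, LogicalVector mask,
                                  IntegerVector dims, int steps) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nxny = (R_xlen_t)nx * ny;
  const R_xlen_t n = nxny * nz;
  LogicalVector out(n);
  std::vector<int> depth(n, -1);
  std::queue<R_xlen_t> q;
  for (R_xlen_t i = 0; i < n; ++i)
    if (seed[i] && mask[i]) { out[i] = TRUE; depth[i] = 0; q.push(i); }
  const int offs_d[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  while (!q.empty()) {
    R_xlen_t i = q.front(); q.pop();
    if (steps >= 0 && depth[i] >= steps) continue;
    int xx = (int)(i % nx), yy = (int)((i / nx) % ny), zz = (int)(i / nxny);
    for (int k = 0; k < 6; ++k) {
      int x2 = xx + offs_d[k][0], y2 = yy + offs_d[k][1], z2 = zz + offs_d[k][2];
      if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz) continue;
      R_xlen_t j = x2 + (R_xlen_t)nx * y2 + nxny * z2;
      if (mask[j] && depth[j] < 0) { depth[j] = depth[i] + 1; out[j] = TRUE; q.push(j); }
    }
  }
  return out;
}

// Mask voxels with at least one face neighbour outside the mask.
// edge_is_boundary: whether the grid edge counts as "outside".
// [[Rcpp::export]]
LogicalVector boundary6_cpp(LogicalVector mask, IntegerVector dims, bool edge_is_boundary) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nxny = (R_xlen_t)nx * ny;
  LogicalVector out((R_xlen_t)nxny * nz);
  for (int zz = 0; zz < nz; ++zz)
    for (int yy = 0; yy < ny; ++yy)
      for (int xx = 0; xx < nx; ++xx) {
        R_xlen_t i = xx + (R_xlen_t)nx * yy + nxny * zz;
        if (!mask[i]) { out[i] = FALSE; continue; }
        bool bd = false;
        if (xx == 0 || xx == nx - 1 || yy == 0 || yy == ny - 1 || zz == 0 || zz == nz - 1) {
          bd = edge_is_boundary;
          if (!bd) {
            if (xx > 0 && !mask[i - 1]) bd = true;
            if (xx < nx - 1 && !mask[i + 1]) bd = true;
            if (yy > 0 && !mask[i - nx]) bd = true;
            if (yy < ny - 1 && !mask[i + nx]) bd = true;
            if (zz > 0 && !mask[i - nxny]) bd = true;
            if (zz < nz - 1 && !mask[i + nxny]) bd = true;
          }
        } else {
          bd = !mask[i - 1] || !mask[i + 1] || !mask[i - nx] || !mask[i + nx] ||
               !mask[i - nxny] || !mask[i + nxny];
        }
        out[i] = bd;
      }
  return out;
}
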