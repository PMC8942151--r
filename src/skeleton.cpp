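#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3D curve thinning with the Bertrand-Malandain simple-point characterisation:
// a border voxel may be deleted iff (a) the object voxels of its 26-neighbourhood
// form exactly one 26-connected component, and (b) the background voxels of its
// 18-neighbourhood form exactly one 6-connected component that is 6-adjacent to
// the centre. Endpoints (<= 1 object neighbour) are preserved to keep centrelines.
// Deletion proceeds in six directional sub-iterations with sequential recheck,
// which keeps the result deterministic and topology-preserving.

static inline int idx27(int dx, int dy, int dz) {
  return (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1);
}

// number of 26-connected components of object voxels in N26 (centre excluded)
static int c_star(const bool nb[27]) {
  bool seen[27] = {false};
  int comp = 0;
  for (int s = 0; s < 27; ++s) {
    if (s == 13 || !nb[s] || seen[s]) continue;
    ++comp;
    // BFS
    int stack[27]; int top = 0;
    stack[top++] = s; seen[s] = true;
    while (top) {
      int c = stack[--top];
      int cx = c % 3 - 1, cy = (c / 3) % 3 - 1, cz = c / 9 - 1;
      for (int t = 0; t < 27; ++t) {
        if (t == 13 || !nb[t] || seen[t]) continue;
        int tx = t % 3 - 1, ty = (t / 3) % 3 - 1, tz = t / 9 - 1;
        if (std::abs(tx - cx) <= 1 && std::abs(ty - cy) <= 1 && std::abs(tz - cz) <= 1)
          { seen[t] = true; stack[top++] = t; }
      }
    }
  }
  return comp;
}

// number of 6-connected components of background voxels within N18 that are
// 6-adjacent to the centre
static int c_bar(const bool nb[27]) {
  bool in18[27] = {false};
  for (int t = 0; t < 27; ++t) {
    int tx = t % 3 - 1, ty = (t / 3) % 3 - 1, tz = t / 9 - 1;
    int a = std::abs(tx) + std::abs(ty) + std::abs(tz);
    if (a >= 1 && a <= 2) in18[t] = true;
  }
  bool seen[27] = {false};
  int comp = 0;
  for (int s = 0; s < 27; ++s) {
    if (!in18[s] || nb[s] || seen[s]) continue;
    // flood this background component within N18 (6-connectivity)
    int stack[27]; int top = 0;
    stack[top++] = s; seen[s] = true;
    bool touches_centre = false;
    while (top) {
      int c = stack[--top];
      int cx = c % 3 - 1, cy = (c / 3) % 3 - 1, cz = c / 9 - 1;
      if (std::abs(cx) + std::abs(cy) + std::abs(cz) == 1) touches_centre = true;
      for (int t = 0; t < 27; ++t) {
        if (!in18[t] || nb[t] || seen[t]) continue;
        int tx = t % 3 - 1, ty = (t / 3) % 3 - 1, tz = t / 9 - 1;
        if (std::abs(tx - cx) + std::abs(ty - cy) + std::abs(tz - cz) == 1)
          { seen[t] = true; stack[top++] = t; }
      }
    }
    if (touches_centre) ++comp;
  }
  return comp;
}

static inline bool is_simple(const bool nb[27]) {
  return c_star(nb) == 1 && c_bar(nb) == 1;
}

// 8-subfield parallel thinning: within one wave only voxels of a single
// parity class (x%2, y%2, z%2) are deleted. No two such voxels are
// 26-adjacent, so deleting them simultaneously cannot invalidate each
// other's simplicity, and the directional "unzipping" of 2-voxel-wide slabs
// that plagues naive sequential deletion cannot occur.
// [[Rcpp::export]]
LogicalVector skeletonize3d_cpp(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nxny = (R_xlen_t)nx * ny;
  const R_xlen_t n = nxny * nz;
  std::vector<char> img(n);
  for (R_xlen_t i = 0; i < n; ++i) img[i] = mask[i] ? 1 : 0;

  auto neighbourhood = [&](int xx, int yy, int zz, bool nb[27]) {
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          int x2 = xx + dx, y2 = yy + dy, z2 = zz + dz;
          bool v = false;
          if (x2 >= 0 && x2 < nx && y2 >= 0 && y2 < ny && z2 >= 0 && z2 < nz)
            v = img[x2 + (R_xlen_t)nx * y2 + nxny * z2] != 0;
          nb[idx27(dx, dy, dz)] = v;
        }
  };
  auto n26 = [&](const bool nb[27]) {
    int c = 0;
    for (int t = 0; t < 27; ++t) if (t != 13 && nb[t]) ++c;
    return c;
  };
  const int dirs[6][3] = {{0,0,-1},{0,0,1},{0,-1,0},{0,1,0},{-1,0,0},{1,0,0}};

  // distance-ordered peeling: only voxels within the current L1-depth shell
  // may be deleted, so the surface erodes inward uniformly and endpoint
  // protection engages only near the medial axis.
  std::vector<int> depth(n, 0);
  {
    const int BIG = nx + ny + nz + 3;
    for (int zz = 0; zz < nz; ++zz)
      for (int yy = 0; yy < ny; ++yy)
        for (int xx = 0; xx < nx; ++xx) {
          R_xlen_t i = xx + (R_xlen_t)nx * yy + nxny * zz;
          if (!img[i]) { depth[i] = 0; continue; }
          int best = BIG;
          best = std::min(best, (xx > 0) ? depth[i - 1] + 1 : 1);
          best = std::min(best, (yy > 0) ? depth[i - nx] + 1 : 1);
          best = std::min(best, (zz > 0) ? depth[i - nxny] + 1 : 1);
          depth[i] = best;
        }
    for (int zz = nz - 1; zz >= 0; --zz)
      for (int yy = ny - 1; yy >= 0; --yy)
        for (int xx = nx - 1; xx >= 0; --xx) {
          R_xlen_t i = xx + (R_xlen_t)nx * yy + nxny * zz;
          if (!img[i]) continue;
          int best = depth[i];
          best = std::min(best, (xx < nx - 1) ? depth[i + 1] + 1 : 1);
          best = std::min(best, (yy < ny - 1) ? depth[i + nx] + 1 : 1);
          best = std::min(best, (zz < nz - 1) ? depth[i + nxny] + 1 : 1);
          depth[i] = best;
        }
  }
  int max_depth = 0;
  for (R_xlen_t i = 0; i < n; ++i) max_depth = std::max(max_depth, depth[i]);

  std::vector<R_xlen_t> wave;
  for (int shell = 1; shell <= max_depth; ++shell) {
    bool changed = true;
    while (changed) {
      changed = false;
      for (int d = 0; d < 6; ++d) {
        const int bd = idx27(dirs[d][0], dirs[d][1], dirs[d][2]);
        for (int sf = 0; sf < 8; ++sf) {
          int px = sf & 1, py = (sf >> 1) & 1, pz = (sf >> 2) & 1;
          wave.clear();
          for (int zz = pz; zz < nz; zz += 2)
            for (int yy = py; yy < ny; yy += 2)
              for (int xx = px; xx < nx; xx += 2) {
                R_xlen_t i = xx + (R_xlen_t)nx * yy + nxny * zz;
                if (!img[i] || depth[i] > shell) continue;
                bool nb[27];
                neighbourhood(xx, yy, zz, nb);
                if (nb[bd]) continue;            // not a border voxel for d
                if (n26(nb) <= 1) continue;      // endpoint or isolated: keep
                if (is_simple(nb)) wave.push_back(i);
              }
          if (!wave.empty()) {
            for (R_xlen_t i : wave) img[i] = 0;
            changed = true;
          }
        }
      }
    }
  }
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = img[i] != 0;
  return out;
}
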