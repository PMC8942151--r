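#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Marker-driven priority flood within a mask: voxels are claimed by the
// marker label whose front reaches them at the lowest relief value (ties
// broken by insertion order). With relief = -EDT this behaves as a
// marker-constrained watershed of the inverted distance transform.
// [[Rcpp::export]]
IntegerVector marker_flood_cpp(NumericVector relief, LogicalVector mask,
                               IntegerVector markers, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nxny = (R_xlen_t)nx * ny;
  const R_xlen_t n = nxny * nz;
  IntegerVector lab(n);

  struct Node {
    double pri; unsigned long ord; R_xlen_t idx; int lab;
  };
  struct Cmp {
    bool operator()(const Node& a, const Node& b) const {
      if (a.pri != b.pri) return a.pri > b.pri;
      return a.ord > b.ord;
    }
  };
  std::priority_queue<Node, std::vector<Node>, Cmp> pq;
  unsigned long ord = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (markers[i] > 0 && mask[i]) {
      lab[i] = markers[i];
      pq.push(Node{relief[i], ord++, i, markers[i]});
    }
  }
  const int offs_d[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  while (!pq.empty()) {
    Node nd = pq.top(); pq.pop();
    R_xlen_t i = nd.idx;
    int xx = (int)(i % nx), yy = (int)((i / nx) % ny), zz = (int)(i / nxny);
    for (int k = 0; k < 6; ++k) {
      int x2 = xx + offs_d[k][0], y2 = yy + offs_d[k][1], z2 = zz + offs_d[k][2];
      if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz) continue;
      R_xlen_t j = x2 + (R_xlen_t)nx * y2 + nxny * z2;
      if (!mask[j] || lab[j]) continue;
      lab[j] = nd.lab;
      pq.push(Node{relief[j], ord++, j, nd.lab});
    }
  }
  return lab;
}
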