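#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>

using namespace Rcpp;

// Exact multi-source Dijkstra over the pixel adjacency graph.
// dims: array dimensions (length 2 or 3, R order: fastest-varying first).
// values: image intensities in R array order.
// seeds: 0-based linear indices of seed pixels.
// offsets: n_off x ndim integer matrix of neighbour displacements.
// Edge cost between adjacent pixels a, b is |I(a) - I(b)| (pure intensity
// cost; flat regions are free to traverse).
// [[Rcpp::export(name = ".dijkstra_geodesic")]]
NumericVector dijkstra_geodesic(NumericVector values, IntegerVector dims,
                                IntegerVector seeds, IntegerMatrix offsets) {
  const int nd = dims.size();
  const R_xlen_t n = values.size();
  std::vector<R_xlen_t> stride(nd);
  stride[0] = 1;
  for (int k = 1; k < nd; ++k) stride[k] = stride[k - 1] * dims[k - 1];

  NumericVector dist(n, R_PosInf);
  typedef std::pair<double, R_xlen_t> Node;
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > heap;

  for (R_xlen_t s = 0; s < seeds.size(); ++s) {
    R_xlen_t idx = seeds[s];
    if (idx < 0 || idx >= n) stop("seed index out of bounds");
    if (dist[idx] > 0.0) {
      dist[idx] = 0.0;
      heap.push(Node(0.0, idx));
    }
  }

  std::vector<int> coord(nd), ncoord(nd);
  while (!heap.empty()) {
    Node top = heap.top();
    heap.pop();
    double d = top.first;
    R_xlen_t u = top.second;
    if (d > dist[u]) continue;  // stale entry
    // unravel u into coordinates
    R_xlen_t rem = u;
    for (int k = nd - 1; k >= 0; --k) {
      coord[k] = (int)(rem / stride[k]);
      rem -= (R_xlen_t)coord[k] * stride[k];
    }
    for (int o = 0; o < offsets.nrow(); ++o) {
      bool ok = true;
      R_xlen_t v = 0;
      for (int k = 0; k < nd; ++k) {
        int c = coord[k] + offsets(o, k);
        if (c < 0 || c >= dims[k]) { ok = false; break; }
        v += (R_xlen_t)c * stride[k];
      }
      if (!ok) continue;
      double w = std::abs(values[u] - values[v]);
      double nd2 = d + w;
      if (nd2 < dist[v]) {
        dist[v] = nd2;
        heap.push(Node(nd2, v));
      }
    }
  }
  return dist;
}
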