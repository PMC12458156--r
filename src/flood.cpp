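#include <Rcpp.h>
#include <queue>
#include <tuple>
using namespace Rcpp;

// Marker-controlled watershed by priority flood on a height map (here the
// Euclidean distance transform; flooding proceeds from high to low, which is
// watershed on the negated map). 8-connected; ties broken by insertion
// order, so results are deterministic.
//
// dist:  height map (only foreground values matter)
// mask:  logical foreground
// seeds: n x 2 matrix of 1-based (row, col) marker positions on foreground
// Returns an integer label matrix; seed k floods label k.
// [[Rcpp::export(name = ".ws_flood")]]
IntegerMatrix ws_flood(NumericMatrix dist, LogicalMatrix mask, IntegerMatrix seeds) {
  const int H = dist.nrow(), W = dist.ncol();
  IntegerMatrix lab(H, W);
  typedef std::tuple<double, long long, int> Node; // (height, -order, index)
  std::priority_queue<Node> pq;
  long long counter = 0;

  for (int s = 0; s < seeds.nrow(); ++s) {
    int r = seeds(s, 0) - 1, c = seeds(s, 1) - 1;
    if (r < 0 || r >= H || c < 0 || c >= W) continue;
    lab(r, c) = s + 1;
    pq.push(Node(dist(r, c), -(counter++), r + c * H));
  }

  const int dr[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc[8] = {0, 0, -1, 1, -1, 1, -1, 1};

  while (!pq.empty()) {
    Node nd = pq.top();
    pq.pop();
    int idx = std::get<2>(nd);
    int r = idx % H, c = idx / H;
    int l = lab(r, c);
    for (int k = 0; k < 8; ++k) {
      int rr = r + dr[k], cc = c + dc[k];
      if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
      if (!mask(rr, cc) || lab(rr, cc) != 0) continue;
      lab(rr, cc) = l;
      pq.push(Node(dist(rr, cc), -(counter++), rr + cc * H));
    }
  }
  return lab;
}
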