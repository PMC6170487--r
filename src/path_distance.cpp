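#include <Rcpp.h>
#include <cmath>
#include <queue>
#include <utility>
#include <vector>
using namespace Rcpp;

// Multi-source Dijkstra on the 8-connected cell lattice.
// Movement is restricted to cells where `allowed` is true (the caller is
// expected to include the source cells in the allowed set).  The weight of
// a step is the 3-D surface length sqrt(h^2 + dz^2) where h is cell_size
// for axial moves and cell_size*sqrt(2) for diagonal moves and dz is the
// elevation difference between the two cell centres.

// [[Rcpp::export]]
NumericMatrix cpp_path_distance(LogicalMatrix allowed, NumericMatrix elevation,
                                LogicalMatrix sources, double cell_size) {
  const int nr = allowed.nrow(), nc = allowed.ncol();
  NumericMatrix dist(nr, nc);
  std::fill(dist.begin(), dist.end(), R_PosInf);

  typedef std::pair<double, int> Node;  // (distance, column-major index)
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;

  const int n = nr * nc;
  for (int idx = 0; idx < n; ++idx)
    if (sources[idx]) { dist[idx] = 0.0; pq.push(Node(0.0, idx)); }

  static const int di[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  static const int dj[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const double diag = cell_size * std::sqrt(2.0);

  while (!pq.empty()) {
    const double d = pq.top().first;
    const int idx = pq.top().second;
    pq.pop();
    if (d > dist[idx]) continue;  // stale entry
    const int i = idx % nr, j = idx / nr;
    for (int k = 0; k < 8; ++k) {
      const int ni = i + di[k], nj = j + dj[k];
      if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
      const int nidx = ni + nj * nr;
      if (!allowed[nidx]) continue;
      const double h = (di[k] != 0 && dj[k] != 0) ? diag : cell_size;
      const double dz = elevation[nidx] - elevation[idx];
      const double nd = d + std::sqrt(h * h + dz * dz);
      if (nd < dist[nidx]) { dist[nidx] = nd; pq.push(Node(nd, nidx)); }
    }
  }
  return dist;
}
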