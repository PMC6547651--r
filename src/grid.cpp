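#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Cost-distance sweeps on a raster under the standard GIS convention:
// 8-connected moves, a move costs the arithmetic mean of the two cell
// costs, times sqrt(2) for diagonal moves.

static const int DR[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

// [[Rcpp::export(name = ".grid_dijkstra_cpp")]]
List grid_dijkstra_cpp(NumericMatrix cost, int src_row, int src_col,
                       double max_cost) {
  const int nr = cost.nrow(), nc = cost.ncol(), n = nr * nc;
  if (src_row < 1 || src_row > nr || src_col < 1 || src_col > nc)
    stop("source cell off the grid");
  std::vector<double> dist(n, R_PosInf);
  std::vector<int> pred(n, NA_INTEGER);
  typedef std::pair<double, int> QE; // (dist, cell index, column-major 0-based)
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  const int s = (src_col - 1) * nr + (src_row - 1);
  dist[s] = 0.0;
  pq.push(QE(0.0, s));
  const double SQRT2 = std::sqrt(2.0);
  while (!pq.empty()) {
    QE top = pq.top();
    pq.pop();
    const double d = top.first;
    const int v = top.second;
    if (d > dist[v]) continue;
    const int r = v % nr, c = v / nr;
    const double cv = cost[v];
    for (int k = 0; k < 8; ++k) {
      const int r2 = r + DR[k], c2 = c + DC[k];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      const int w = c2 * nr + r2;
      double step = 0.5 * (cv + cost[w]);
      if (DR[k] != 0 && DC[k] != 0) step *= SQRT2;
      const double d2 = d + step;
      if (d2 <= max_cost && d2 < dist[w]) {
        dist[w] = d2;
        pred[w] = v + 1; // 1-based for R
        pq.push(QE(d2, w));
      }
    }
  }
  NumericMatrix dm(nr, nc);
  IntegerMatrix pm(nr, nc);
  for (int i = 0; i < n; ++i) {
    dm[i] = dist[i];
    pm[i] = pred[i];
  }
  return List::create(_["dist"] = dm, _["pred"] = pm);
}

// Connected-component labels of a logical mask (4- or 8-connectivity),
// 0 for background, components numbered from 1.
// [[Rcpp::export(name = ".cc_label_cpp")]]
IntegerMatrix cc_label_cpp(LogicalMatrix mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int nr = mask.nrow(), nc = mask.ncol(), n = nr * nc;
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  std::vector<int> stack;
  int next = 0;
  const int nk = connectivity;
  // 4-connectivity uses the non-diagonal subset of (DR, DC)
  const int K4[4] = {1, 3, 4, 6};
  for (int i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      const int v = stack.back();
      stack.pop_back();
      const int r = v % nr, c = v / nr;
      for (int kk = 0; kk < nk; ++kk) {
        const int k = (connectivity == 4) ? K4[kk] : kk;
        const int r2 = r + DR[k], c2 = c + DC[k];
        if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
        const int w = c2 * nr + r2;
        if (mask[w] && lab[w] == 0) {
          lab[w] = next;
          stack.push_back(w);
        }
      }
    }
  }
  return lab;
}
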