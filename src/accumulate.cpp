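#include <Rcpp.h>
#include <queue>
#include <tuple>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Multi-source Dijkstra over a friction grid.
//
// friction: minutes per meter, NA = impassable. Edge between adjacent cells
// a,b costs ((f(a)+f(b))/2) * d(a,b), d = cell_size for orthogonal steps,
// cell_size*sqrt(2) for diagonal steps, cell_size*sqrt(5) for knight steps
// (16-connectivity). Ties on the heap break on lowest (row, col) so output
// is bit-reproducible.
//
// Returns minutes; +Inf for passable cells with no path, NA where friction
// is NA.
// [[Rcpp::export(name = ".dijkstra_accumulate")]]
NumericMatrix dijkstra_accumulate(NumericMatrix friction,
                                  IntegerVector src_row,
                                  IntegerVector src_col,
                                  double cell_size,
                                  int connectivity) {
  const int nr = friction.nrow(), nc = friction.ncol();
  if (src_row.size() == 0)
    stop("source set is empty");
  if (connectivity != 4 && connectivity != 8 && connectivity != 16)
    stop("connectivity must be 4, 8 or 16");

  std::vector<int> dr, dc;
  std::vector<double> dd;
  const double s2 = std::sqrt(2.0), s5 = std::sqrt(5.0);
  int odr[4] = {-1, 0, 0, 1}, odc[4] = {0, -1, 1, 0};
  for (int k = 0; k < 4; ++k) {
    dr.push_back(odr[k]); dc.push_back(odc[k]); dd.push_back(1.0);
  }
  if (connectivity >= 8) {
    int xdr[4] = {-1, -1, 1, 1}, xdc[4] = {-1, 1, -1, 1};
    for (int k = 0; k < 4; ++k) {
      dr.push_back(xdr[k]); dc.push_back(xdc[k]); dd.push_back(s2);
    }
  }
  if (connectivity == 16) {
    int kdr[8] = {-2, -2, -1, -1, 1, 1, 2, 2};
    int kdc[8] = {-1, 1, -2, 2, -2, 2, -1, 1};
    for (int k = 0; k < 8; ++k) {
      dr.push_back(kdr[k]); dc.push_back(kdc[k]); dd.push_back(s5);
    }
  }

  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> dist((size_t)nr * nc, INF);
  std::vector<bool> settled((size_t)nr * nc, false);

  typedef std::tuple<double, int, int> Node;  // (dist, row, col)
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;

  for (int i = 0; i < src_row.size(); ++i) {
    int r = src_row[i], c = src_col[i];
    if (r < 0 || r >= nr || c < 0 || c >= nc)
      stop("source cell out of grid bounds");
    if (NumericMatrix::is_na(friction(r, c)))
      stop("source cell sits on impassable (nodata) friction");
    size_t idx = (size_t)r * nc + c;
    if (dist[idx] > 0.0) {
      dist[idx] = 0.0;
      pq.push(Node(0.0, r, c));
    }
  }

  while (!pq.empty()) {
    Node top = pq.top(); pq.pop();
    double d = std::get<0>(top);
    int r = std::get<1>(top), c = std::get<2>(top);
    size_t idx = (size_t)r * nc + c;
    if (settled[idx]) continue;
    settled[idx] = true;
    double fr = friction(r, c);
    for (size_t k = 0; k < dr.size(); ++k) {
      int r2 = r + dr[k], c2 = c + dc[k];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      double f2 = friction(r2, c2);
      if (NumericMatrix::is_na(f2)) continue;
      size_t idx2 = (size_t)r2 * nc + c2;
      if (settled[idx2]) continue;
      double nd = d + 0.5 * (fr + f2) * dd[k] * cell_size;
      if (nd < dist[idx2]) {
        dist[idx2] = nd;
        pq.push(Node(nd, r2, c2));
      }
    }
  }

  NumericMatrix out(nr, nc);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c)
      out(r, c) = NumericMatrix::is_na(friction(r, c))
        ? NA_REAL : dist[(size_t)r * nc + c];
  return out;
}
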