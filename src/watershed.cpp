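#include <Rcpp.h>
#include <queue>
#include <tuple>
using namespace Rcpp;

// Meyer's priority-flood watershed with markers. `relief` is the surface to
// flood (the caller passes the inverted CHM so treetops are minima),
// `markers` holds positive seed labels (0 elsewhere), `mask` marks cells
// eligible for labelling. Ties are broken by insertion order so results are
// deterministic.

// [[Rcpp::export]]
IntegerMatrix watershed_flood_cpp(NumericMatrix relief, IntegerMatrix markers,
                                  LogicalMatrix mask) {
  const int nr = relief.nrow(), nc = relief.ncol();
  if (markers.nrow() != nr || markers.ncol() != nc ||
      mask.nrow() != nr || mask.ncol() != nc)
    stop("relief, markers and mask must have identical dimensions");

  IntegerMatrix labels(nr, nc);
  using Node = std::tuple<double, long long, int, int>; // value, order, r, c
  std::priority_queue<Node, std::vector<Node>, std::greater<Node>> pq;
  long long order = 0;

  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      labels(r, c) = 0;
      if (markers(r, c) > 0) {
        if (!mask(r, c)) stop("marker placed on a masked-out cell");
        labels(r, c) = markers(r, c);
        pq.emplace(relief(r, c), order++, r, c);
      }
    }
  if (order == 0) stop("no markers supplied");

  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  while (!pq.empty()) {
    auto [val, ord, r, c] = pq.top(); pq.pop();
    (void)val; (void)ord;
    int lab = labels(r, c);
    for (int k = 0; k < 8; ++k) {
      int r2 = r + dr[k], c2 = c + dc[k];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      if (!mask(r2, c2) || labels(r2, c2) != 0) continue;
      labels(r2, c2) = lab;
      pq.emplace(relief(r2, c2), order++, r2, c2);
    }
  }
  return labels;
}
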