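#include <Rcpp.h>
#include <queue>
#include <vector>

using namespace Rcpp;

// Seeded watershed by priority flooding on an elevation map, restricted to a
// binary mask. Seeds are flooded from their own pixels; the queue pops the
// lowest elevation first, ties broken by linear pixel index, so the labelling
// is fully deterministic. 8-connected.
struct QEntry {
  double elev;
  int idx;
  int label;
};

struct QCompare {
  bool operator()(const QEntry &a, const QEntry &b) const {
    if (a.elev != b.elev) return a.elev > b.elev; // min-heap on elevation
    return a.idx > b.idx;                         // then lowest linear index
  }
};

// [[Rcpp::export(name = ".watershedFlood")]]
IntegerMatrix watershedFlood(NumericMatrix elevation, LogicalMatrix mask,
                             IntegerMatrix seeds) {
  const int nx = elevation.nrow(), ny = elevation.ncol();
  IntegerMatrix labels(nx, ny);
  std::priority_queue<QEntry, std::vector<QEntry>, QCompare> pq;

  for (int s = 0; s < seeds.nrow(); ++s) {
    int x = seeds(s, 0) - 1, y = seeds(s, 1) - 1;
    if (x < 0 || x >= nx || y < 0 || y >= ny) continue;
    if (!mask(x, y)) continue;
    if (labels(x, y) != 0) continue; // first seed wins a shared pixel
    labels(x, y) = seeds(s, 2);
    pq.push({elevation(x, y), x + y * nx, seeds(s, 2)});
  }

  const int dx[8] = {1, 1, 0, -1, -1, -1, 0, 1};
  const int dy[8] = {0, 1, 1, 1, 0, -1, -1, -1};

  while (!pq.empty()) {
    QEntry e = pq.top();
    pq.pop();
    int x = e.idx % nx, y = e.idx / nx;
    for (int d = 0; d < 8; ++d) {
      int px = x + dx[d], py = y + dy[d];
      if (px < 0 || px >= nx || py < 0 || py >= ny) continue;
      if (!mask(px, py) || labels(px, py) != 0) continue;
      labels(px, py) = e.label;
      pq.push({elevation(px, py), px + py * nx, e.label});
    }
  }
  return labels;
}
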