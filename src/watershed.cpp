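#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Seeded priority-flood (Meyer) watershed: basins grow from marker pixels in
// order of increasing priority (gradient magnitude). A pixel may be queued by
// several basins; the first pop (lowest priority, FIFO on ties) claims it.

struct Node {
  double p;
  long long ord;
  int idx;
  int lab;
};

struct NodeCmp {
  bool operator()(const Node &a, const Node &b) const {
    if (a.p != b.p) return a.p > b.p;
    return a.ord > b.ord;
  }
};

// [[Rcpp::export]]
IntegerMatrix watershed_flood(NumericMatrix priority, IntegerMatrix markers) {
  const int nr = priority.nrow(), nc = priority.ncol();
  if (markers.nrow() != nr || markers.ncol() != nc)
    stop("priority and markers must have identical dimensions");
  IntegerMatrix lab(nr, nc);
  std::priority_queue<Node, std::vector<Node>, NodeCmp> q;
  long long ord = 0;

  const int dr[4] = {-1, 1, 0, 0};
  const int dc[4] = {0, 0, -1, 1};

  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (markers(r, c) > 0) lab(r, c) = markers(r, c);

  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (lab(r, c) > 0)
        for (int k = 0; k < 4; ++k) {
          int rr = r + dr[k], cc = c + dc[k];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (lab(rr, cc) == 0)
            q.push({priority(rr, cc), ord++, rr + cc * nr, lab(r, c)});
        }

  while (!q.empty()) {
    Node nd = q.top();
    q.pop();
    int r = nd.idx % nr, c = nd.idx / nr;
    if (lab(r, c) != 0) continue;
    lab(r, c) = nd.lab;
    for (int k = 0; k < 4; ++k) {
      int rr = r + dr[k], cc = c + dc[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (lab(rr, cc) == 0)
        q.push({priority(rr, cc), ord++, rr + cc * nr, lab(r, c)});
    }
  }
  return lab;
}
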