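#include <Rcpp.h>
#include <queue>
#include <limits>
using namespace Rcpp;

// Two-pass 8-connected component labelling (union-find).
// Labels are positive integers in row-major first-encounter order.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(const IntegerMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent(1, 0); // parent[0] unused

  auto find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  };

  int next = 0;
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      if (!mask(i, j)) continue;
      // previously-scanned 8-neighbours: W, NW, N, NE
      int best = 0;
      const int di[4] = {0, -1, -1, -1};
      const int dj[4] = {-1, -1, 0, 1};
      int nb[4], k = 0;
      for (int t = 0; t < 4; ++t) {
        int ii = i + di[t], jj = j + dj[t];
        if (ii < 0 || jj < 0 || jj >= nc) continue;
        int l = lab(ii, jj);
        if (l > 0) { nb[k++] = l; if (best == 0 || l < best) best = l; }
      }
      if (best == 0) {
        parent.push_back(++next);
        lab(i, j) = next;
      } else {
        lab(i, j) = best;
        for (int t = 0; t < k; ++t) unite(best, nb[t]);
      }
    }
  }

  // flatten and renumber 1..n in first-encounter order
  std::vector<int> newlab(next + 1, 0);
  int n = 0;
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j)
      if (lab(i, j) > 0) {
        int r = find(lab(i, j));
        if (newlab[r] == 0) newlab[r] = ++n;
        lab(i, j) = newlab[r];
      }
  lab.attr("n_labels") = n;
  return lab;
}

// Chamfer 3-4 distance transform, normalised by 3.
// Background (mask == 0) is exactly 0; foreground gets the two-pass
// propagated distance to the nearest background pixel.
// [[Rcpp::export]]
NumericMatrix chamfer_cpp(const IntegerMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const int INF = std::numeric_limits<int>::max() / 4;
  std::vector<int> d(static_cast<size_t>(nr) * nc);
  auto at = [&](int i, int j) -> int& { return d[static_cast<size_t>(j) * nr + i]; };

  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j)
      at(i, j) = mask(i, j) ? INF : 0;

  // forward pass: W+3, NW+4, N+3, NE+4
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j) {
      if (!mask(i, j)) continue;
      int v = at(i, j);
      if (j > 0)                v = std::min(v, at(i, j - 1) + 3);
      if (i > 0) {
        v = std::min(v, at(i - 1, j) + 3);
        if (j > 0)              v = std::min(v, at(i - 1, j - 1) + 4);
        if (j < nc - 1)         v = std::min(v, at(i - 1, j + 1) + 4);
      }
      at(i, j) = v;
    }
  // backward pass: E+3, SE+4, S+3, SW+4
  for (int i = nr - 1; i >= 0; --i)
    for (int j = nc - 1; j >= 0; --j) {
      if (!mask(i, j)) continue;
      int v = at(i, j);
      if (j < nc - 1)           v = std::min(v, at(i, j + 1) + 3);
      if (i < nr - 1) {
        v = std::min(v, at(i + 1, j) + 3);
        if (j < nc - 1)         v = std::min(v, at(i + 1, j + 1) + 4);
        if (j > 0)              v = std::min(v, at(i + 1, j - 1) + 4);
      }
      at(i, j) = v;
    }

  NumericMatrix out(nr, nc);
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j)
      out(i, j) = at(i, j) / 3.0;
  return out;
}

struct WsNode {
  double prio;    // flooding surface value (lower floods later)
  long long ord;  // insertion order, FIFO tie-break
  int i, j, lab;
};
struct WsCmp {
  bool operator()(const WsNode& a, const WsNode& b) const {
    if (a.prio != b.prio) return a.prio < b.prio; // max-heap on distance
    return a.ord > b.ord;                         // earlier insert first
  }
};

// Marker-seeded watershed by priority flooding of the negated distance map:
// basins grow from markers, highest distance first, until the mask foreground
// is partitioned. 8-connected growth.
// [[Rcpp::export]]
IntegerMatrix watershed_cpp(const NumericMatrix& dist, const IntegerMatrix& mask,
                            const IntegerMatrix& markers) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix out(nr, nc);
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  long long ord = 0;

  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (markers(i, j) > 0 && mask(i, j)) {
        out(i, j) = markers(i, j);
        pq.push({dist(i, j), ord++, i, j, markers(i, j)});
      }

  const int di[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dj[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  while (!pq.empty()) {
    WsNode n = pq.top(); pq.pop();
    for (int t = 0; t < 8; ++t) {
      int ii = n.i + di[t], jj = n.j + dj[t];
      if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
      if (!mask(ii, jj) || out(ii, jj) > 0) continue;
      out(ii, jj) = n.lab;
      pq.push({dist(ii, jj), ord++, ii, jj, n.lab});
    }
  }
  return out;
}
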