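#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <deque>
#include <algorithm>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Grid-bucketed DBSCAN on planar points.
//
// Semantics (fully deterministic, order-independent):
//  * a core point has >= min_pts neighbours within distance eps (inclusive,
//    counting itself);
//  * clusters are the connected components of core points under the
//    within-eps relation, numbered by the lexicographic (x, y) rank of their
//    first core point;
//  * a border point (non-core within eps of >= 1 core) joins the cluster of
//    its lowest-ranked core neighbour;
//  * remaining points are noise.
//
// Returns integer labels in input order: 0 = noise, clusters 1..k.

static inline int64_t cell_key(int cx, int cy) {
  return (static_cast<int64_t>(cx) << 32) ^ (static_cast<int64_t>(cy) & 0xffffffffLL);
}

// [[Rcpp::export(name = ".dbscan_cpp")]]
IntegerVector dbscan_cpp(NumericVector x, NumericVector y, double eps, int min_pts) {
  const int n = x.size();
  IntegerVector labels(n, 0);
  if (n == 0) return labels;

  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (x[a] != x[b]) return x[a] < x[b];
    return y[a] < y[b];
  });
  std::vector<int> rank(n);
  for (int i = 0; i < n; ++i) rank[ord[i]] = i;

  std::unordered_map<int64_t, std::vector<int>> grid;
  grid.reserve(2 * n);
  const double inv_eps = 1.0 / eps;
  std::vector<int> cxv(n), cyv(n);
  for (int i = 0; i < n; ++i) {
    cxv[i] = static_cast<int>(std::floor(x[i] * inv_eps));
    cyv[i] = static_cast<int>(std::floor(y[i] * inv_eps));
    grid[cell_key(cxv[i], cyv[i])].push_back(i);
  }

  const double eps2 = eps * eps;
  auto region_query = [&](int i, std::vector<int> &out) {
    out.clear();
    for (int dx = -1; dx <= 1; ++dx) {
      for (int dy = -1; dy <= 1; ++dy) {
        auto it = grid.find(cell_key(cxv[i] + dx, cyv[i] + dy));
        if (it == grid.end()) continue;
        for (int j : it->second) {
          const double ddx = x[j] - x[i], ddy = y[j] - y[i];
          if (ddx * ddx + ddy * ddy <= eps2) out.push_back(j);
        }
      }
    }
  };

  // pass 1: core flags
  std::vector<char> core(n, 0);
  {
    std::vector<int> nb;
    nb.reserve(64);
    for (int i = 0; i < n; ++i) {
      region_query(i, nb);
      core[i] = static_cast<int>(nb.size()) >= min_pts;
    }
  }

  // pass 2: connected components of core points, seeded in lex order
  int n_clusters = 0;
  std::vector<int> nb;
  for (int oi = 0; oi < n; ++oi) {
    const int i = ord[oi];
    if (!core[i] || labels[i] != 0) continue;
    ++n_clusters;
    labels[i] = n_clusters;
    std::deque<int> seeds = {i};
    while (!seeds.empty()) {
      const int q = seeds.front();
      seeds.pop_front();
      region_query(q, nb);
      for (int r : nb) {
        if (core[r] && labels[r] == 0) {
          labels[r] = n_clusters;
          seeds.push_back(r);
        }
      }
    }
  }

  // pass 3: border points -> cluster of the lowest-ranked core neighbour
  for (int i = 0; i < n; ++i) {
    if (core[i] || labels[i] != 0) continue;
    region_query(i, nb);
    int best = -1;
    for (int r : nb) {
      if (core[r] && (best < 0 || rank[r] < rank[best])) best = r;
    }
    if (best >= 0) labels[i] = labels[best];
  }
  return labels;
}
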