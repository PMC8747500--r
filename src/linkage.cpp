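#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Disjoint-set forest with path halving and union by size.
static int find_root(std::vector<int> &parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void unite(std::vector<int> &parent, std::vector<int> &sz, int a, int b) {
  a = find_root(parent, a);
  b = find_root(parent, b);
  if (a == b) return;
  if (sz[a] < sz[b]) std::swap(a, b);
  parent[b] = a;
  sz[a] += sz[b];
}

// Connected components of the graph linking every pair of points at
// Euclidean distance STRICTLY below `threshold` (single-linkage cut with a
// strict inequality: points exactly at the threshold are not merged).
// Neighbor search uses grid bucketing at cell size = threshold, so only the
// 3x3 cell neighborhood of each point is scanned; the result equals the
// all-pairs definition. Labels are positive integers, contiguous 1..k in
// order of first appearance, making the labeling deterministic for a given
// record order while the partition itself is order-invariant.
// [[Rcpp::export]]
IntegerVector strict_linkage_components(NumericVector x, NumericVector y,
                                        double threshold) {
  const int n = x.size();
  IntegerVector labels(n);
  if (n == 0) return labels;
  if (!(threshold > 0)) stop("threshold must be positive");

  const double t2 = threshold * threshold;
  double xmin = x[0], ymin = y[0];
  for (int i = 1; i < n; ++i) {
    if (x[i] < xmin) xmin = x[i];
    if (y[i] < ymin) ymin = y[i];
  }

  std::vector<int> parent(n), sz(n, 1);
  for (int i = 0; i < n; ++i) parent[i] = i;

  std::unordered_map<long long, std::vector<int> > grid;
  grid.reserve(2 * n);
  const long long STRIDE = 1LL << 32;

  for (int i = 0; i < n; ++i) {
    const long long cx = (long long)std::floor((x[i] - xmin) / threshold);
    const long long cy = (long long)std::floor((y[i] - ymin) / threshold);
    for (long long dx = -1; dx <= 1; ++dx) {
      for (long long dy = -1; dy <= 1; ++dy) {
        std::unordered_map<long long, std::vector<int> >::iterator it =
            grid.find((cx + dx) * STRIDE + (cy + dy));
        if (it == grid.end()) continue;
        const std::vector<int> &bucket = it->second;
        for (size_t k = 0; k < bucket.size(); ++k) {
          const int j = bucket[k];
          const double ddx = x[i] - x[j], ddy = y[i] - y[j];
          if (ddx * ddx + ddy * ddy < t2) unite(parent, sz, i, j);
        }
      }
    }
    grid[cx * STRIDE + cy].push_back(i);
  }

  std::unordered_map<int, int> relabel;
  relabel.reserve(n);
  int next = 0;
  for (int i = 0; i < n; ++i) {
    const int r = find_root(parent, i);
    std::unordered_map<int, int>::iterator it = relabel.find(r);
    if (it == relabel.end()) {
      relabel[r] = ++next;
      labels[i] = next;
    } else {
      labels[i] = it->second;
    }
  }
  return labels;
}

// Minimum Euclidean distance between two point sets (brute force; used for
// cluster-coupling gaps where sets are single-cluster sized).
// [[Rcpp::export]]
double min_cross_distance(NumericVector ax, NumericVector ay,
                          NumericVector bx, NumericVector by) {
  const int na = ax.size(), nb = bx.size();
  if (na == 0 || nb == 0) return R_PosInf;
  double best = R_PosInf;
  for (int i = 0; i < na; ++i) {
    for (int j = 0; j < nb; ++j) {
      const double dx = ax[i] - bx[j], dy = ay[i] - by[j];
      const double d2 = dx * dx + dy * dy;
      if (d2 < best) best = d2;
    }
  }
  return std::sqrt(best);
}
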