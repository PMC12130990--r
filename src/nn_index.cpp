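// Spatial nearest-neighbor backends for centroid matching.
//
// Two index structures over a fixed 2-D point set:
//   * KdTree      -- exact nearest neighbor, deterministic, smallest-index
//                    tie-break on equal distance.
//   * RpForest    -- Annoy-style approximate index: a forest of random
//                    projection trees (each internal node splits the points by
//                    the perpendicular-bisector hyperplane of two randomly
//                    chosen members), searched with a single priority queue
//                    over hyperplane margins until search_k candidates have
//                    been inspected.
//
// Indices are 0-based internally; the R wrappers convert to 1-based. A query
// against an empty index returns index 0 with distance Inf (sentinel handled
// on the R side).

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <limits>
#include <queue>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

struct Pt {
  double x, y;
};

inline double sqdist(const Pt& a, double qx, double qy) {
  const double dx = a.x - qx, dy = a.y - qy;
  return dx * dx + dy * dy;
}

// ---------------------------------------------------------------- exact k-d

class KdTree {
 public:
  explicit KdTree(const std::vector<Pt>& pts) : pts_(pts) {
    const int n = static_cast<int>(pts_.size());
    order_.resize(n);
    for (int i = 0; i < n; ++i) order_[i] = i;
    if (n > 0) build(0, n, 0);
  }

  // Returns {index, squared distance}; index -1 when empty.
  std::pair<int, double> nearest(double qx, double qy) const {
    if (pts_.empty()) return {-1, std::numeric_limits<double>::infinity()};
    int best = -1;
    double bestd = std::numeric_limits<double>::infinity();
    search(0, static_cast<int>(pts_.size()), 0, qx, qy, best, bestd);
    return {best, bestd};
  }

 private:
  // Median split on alternating axes over order_[lo, hi).
  void build(int lo, int hi, int axis) {
    if (hi - lo <= 1) return;
    const int mid = lo + (hi - lo) / 2;
    const std::vector<Pt>& p = pts_;
    std::nth_element(order_.begin() + lo, order_.begin() + mid,
                     order_.begin() + hi, [&p, axis](int a, int b) {
                       const double va = axis == 0 ? p[a].x : p[a].y;
                       const double vb = axis == 0 ? p[b].x : p[b].y;
                       if (va != vb) return va < vb;
                       return a < b;  // deterministic layout for duplicates
                     });
    build(lo, mid, 1 - axis);
    build(mid + 1, hi, 1 - axis);
  }

  void consider(int idx, double qx, double qy, int& best, double& bestd) const {
    const double d = sqdist(pts_[idx], qx, qy);
    if (d < bestd || (d == bestd && idx < best)) {
      bestd = d;
      best = idx;
    }
  }

  void search(int lo, int hi, int axis, double qx, double qy, int& best,
              double& bestd) const {
    if (lo >= hi) return;
    const int mid = lo + (hi - lo) / 2;
    const int idx = order_[mid];
    consider(idx, qx, qy, best, bestd);
    const double q = axis == 0 ? qx : qy;
    const double v = axis == 0 ? pts_[idx].x : pts_[idx].y;
    const double gap = q - v;
    const bool left_first = gap < 0;
    if (left_first) {
      search(lo, mid, 1 - axis, qx, qy, best, bestd);
      if (gap * gap <= bestd) search(mid + 1, hi, 1 - axis, qx, qy, best, bestd);
    } else {
      search(mid + 1, hi, 1 - axis, qx, qy, best, bestd);
      if (gap * gap <= bestd) search(lo, mid, 1 - axis, qx, qy, best, bestd);
    }
  }

  std::vector<Pt> pts_;
  std::vector<int> order_;
};

// -------------------------------------------------- Annoy-style RP forest

struct RpNode {
  // leaf: items holds point indices; internal: hyperplane n.x*x+n.y*y = off
  std::vector<int> items;
  double nx = 0, ny = 0, off = 0;
  int left = -1, right = -1;
  bool is_leaf() const { return left < 0; }
};

class RpForest {
 public:
  RpForest(const std::vector<Pt>& pts, int n_trees, int leaf_size,
           unsigned int seed)
      : pts_(pts), leaf_size_(std::max(2, leaf_size)), rng_(seed) {
    roots_.reserve(n_trees);
    std::vector<int> all(pts_.size());
    for (size_t i = 0; i < pts_.size(); ++i) all[i] = static_cast<int>(i);
    for (int t = 0; t < n_trees; ++t) {
      if (pts_.empty()) {
        roots_.push_back(-1);
      } else {
        std::vector<int> items(all);
        roots_.push_back(build(items, 0));
      }
    }
  }

  std::pair<int, double> nearest(double qx, double qy, int search_k) const {
    if (pts_.empty()) return {-1, std::numeric_limits<double>::infinity()};
    if (search_k < 0) search_k = static_cast<int>(roots_.size());  // Annoy default, k = 1
    // max-heap on priority: explore the largest-margin path first
    typedef std::pair<double, int> QE;  // (priority, node id)
    std::priority_queue<QE> pq;
    const double inf = std::numeric_limits<double>::infinity();
    for (int r : roots_)
      if (r >= 0) pq.push({inf, r});
    std::vector<int> cand;
    cand.reserve(search_k + leaf_size_);
    while (!pq.empty() && static_cast<int>(cand.size()) < search_k) {
      const QE top = pq.top();
      pq.pop();
      const RpNode& nd = nodes_[top.second];
      if (nd.is_leaf()) {
        cand.insert(cand.end(), nd.items.begin(), nd.items.end());
      } else {
        const double m = nd.nx * qx + nd.ny * qy - nd.off;
        pq.push({std::min(top.first, m), nd.right});
        pq.push({std::min(top.first, -m), nd.left});
      }
    }
    int best = -1;
    double bestd = inf;
    for (int idx : cand) {
      const double d = sqdist(pts_[idx], qx, qy);
      if (d < bestd || (d == bestd && idx < best)) {
        bestd = d;
        best = idx;
      }
    }
    return {best, bestd};
  }

 private:
  int build(std::vector<int>& items, int depth) {
    const int id = static_cast<int>(nodes_.size());
    nodes_.push_back(RpNode());
    if (static_cast<int>(items.size()) <= leaf_size_ || depth > 50) {
      nodes_[id].items = items;
      return id;
    }
    // split by perpendicular bisector of two distinct random members
    std::uniform_int_distribution<int> pick(0, static_cast<int>(items.size()) - 1);
    double nx = 0, ny = 0, off = 0;
    bool ok = false;
    for (int attempt = 0; attempt < 10 && !ok; ++attempt) {
      const Pt& a = pts_[items[pick(rng_)]];
      const Pt& b = pts_[items[pick(rng_)]];
      nx = a.x - b.x;
      ny = a.y - b.y;
      const double nrm = std::sqrt(nx * nx + ny * ny);
      if (nrm > 0) {
        nx /= nrm;
        ny /= nrm;
        off = nx * 0.5 * (a.x + b.x) + ny * 0.5 * (a.y + b.y);
        ok = true;
      }
    }
    std::vector<int> left, right;
    if (ok) {
      for (int idx : items) {
        const double m = nx * pts_[idx].x + ny * pts_[idx].y - off;
        (m <= 0 ? left : right).push_back(idx);
      }
    }
    if (!ok || left.empty() || right.empty()) {
      // degenerate (coincident points): split arbitrarily in half
      left.assign(items.begin(), items.begin() + items.size() / 2);
      right.assign(items.begin() + items.size() / 2, items.end());
      nx = 1;
      ny = 0;
      off = left.empty() ? 0 : pts_[left[0]].x;
    }
    items.clear();
    items.shrink_to_fit();
    const int l = build(left, depth + 1);
    const int r = build(right, depth + 1);
    nodes_[id].nx = nx;
    nodes_[id].ny = ny;
    nodes_[id].off = off;
    nodes_[id].left = l;
    nodes_[id].right = r;
    return id;
  }

  std::vector<Pt> pts_;
  int leaf_size_;
  std::mt19937 rng_;
  std::vector<int> roots_;
  std::vector<RpNode> nodes_;
};

std::vector<Pt> as_points(NumericVector x, NumericVector y) {
  if (x.size() != y.size()) stop("coordinate vectors differ in length");
  std::vector<Pt> pts(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) pts[i] = {x[i], y[i]};
  return pts;
}

List query_result(const std::vector<std::pair<int, double>>& hits) {
  const R_xlen_t n = hits.size();
  IntegerVector idx(n);
  NumericVector dist(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (hits[i].first < 0) {
      idx[i] = NA_INTEGER;
      dist[i] = R_PosInf;
    } else {
      idx[i] = hits[i].first + 1;
      dist[i] = std::sqrt(hits[i].second);
    }
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}

}  // namespace

// [[Rcpp::export]]
SEXP cpp_kd_build(NumericVector x, NumericVector y) {
  XPtr<KdTree> ptr(new KdTree(as_points(x, y)), true);
  return ptr;
}

// [[Rcpp::export]]
List cpp_kd_query(SEXP handle, NumericVector qx, NumericVector qy) {
  XPtr<KdTree> tree(handle);
  std::vector<std::pair<int, double>> hits(qx.size());
  for (R_xlen_t i = 0; i < qx.size(); ++i) hits[i] = tree->nearest(qx[i], qy[i]);
  return query_result(hits);
}

// [[Rcpp::export]]
SEXP cpp_rp_build(NumericVector x, NumericVector y, int n_trees, int leaf_size,
                  int seed) {
  XPtr<RpForest> ptr(
      new RpForest(as_points(x, y), n_trees, leaf_size,
                   static_cast<unsigned int>(seed)),
      true);
  return ptr;
}

// [[Rcpp::export]]
List cpp_rp_query(SEXP handle, NumericVector qx, NumericVector qy, int search_k) {
  XPtr<RpForest> forest(handle);
  std::vector<std::pair<int, double>> hits(qx.size());
  for (R_xlen_t i = 0; i < qx.size(); ++i)
    hits[i] = forest->nearest(qx[i], qy[i], search_k);
  return query_result(hits);
}
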