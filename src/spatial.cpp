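#include <Rcpp.h>
#include <algorithm>
#include <queue>
#include <vector>
using namespace Rcpp;

// Exact 3-d kd-tree nearest-neighbour lookup. Ties on distance are broken by
// the lowest reference-point index so results are fully deterministic.

namespace {

struct KDNode {
  int idx;
  int axis;
  int left;
  int right;
};

class KDTree {
public:
  explicit KDTree(const NumericMatrix& p) : pts_(p), root_(-1) {
    const int n = p.nrow();
    std::vector<int> id(n);
    for (int i = 0; i < n; ++i) id[i] = i;
    nodes_.reserve(n);
    root_ = build(id, 0, n, 0);
  }

  void query(double x, double y, double z, double& best_d2, int& best_idx) const {
    best_d2 = R_PosInf;
    best_idx = -1;
    search(root_, x, y, z, best_d2, best_idx);
  }

private:
  const NumericMatrix& pts_;
  std::vector<KDNode> nodes_;
  int root_;

  int build(std::vector<int>& id, int lo, int hi, int depth) {
    if (lo >= hi) return -1;
    const int axis = depth % 3;
    const int mid = (lo + hi) / 2;
    std::nth_element(id.begin() + lo, id.begin() + mid, id.begin() + hi,
                     [&](int a, int b) {
                       if (pts_(a, axis) != pts_(b, axis))
                         return pts_(a, axis) < pts_(b, axis);
                       return a < b;
                     });
    KDNode nd;
    nd.idx = id[mid];
    nd.axis = axis;
    nd.left = -1;
    nd.right = -1;
    const int me = static_cast<int>(nodes_.size());
    nodes_.push_back(nd);
    nodes_[me].left = build(id, lo, mid, depth + 1);
    nodes_[me].right = build(id, mid + 1, hi, depth + 1);
    return me;
  }

  void consider(int idx, double x, double y, double z,
                double& best_d2, int& best_idx) const {
    const double dx = pts_(idx, 0) - x;
    const double dy = pts_(idx, 1) - y;
    const double dz = pts_(idx, 2) - z;
    const double d2 = dx * dx + dy * dy + dz * dz;
    if (d2 < best_d2 || (d2 == best_d2 && idx < best_idx)) {
      best_d2 = d2;
      best_idx = idx;
    }
  }

  void search(int node, double x, double y, double z,
              double& best_d2, int& best_idx) const {
    if (node < 0) return;
    const KDNode& nd = nodes_[node];
    consider(nd.idx, x, y, z, best_d2, best_idx);
    const double q = (nd.axis == 0) ? x : (nd.axis == 1) ? y : z;
    const double split = pts_(nd.idx, nd.axis);
    const double diff = q - split;
    const int near = (diff <= 0) ? nd.left : nd.right;
    const int far = (diff <= 0) ? nd.right : nd.left;
    search(near, x, y, z, best_d2, best_idx);
    if (diff * diff <= best_d2) search(far, x, y, z, best_d2, best_idx);
  }
};

}  // namespace

// [[Rcpp::export(name = ".nn_lookup")]]
List nn_lookup(NumericMatrix reference, NumericMatrix query) {
  if (reference.nrow() == 0) stop("empty reference cloud");
  if (reference.ncol() != 3 || query.ncol() != 3)
    stop("point matrices must have 3 columns");
  KDTree tree(reference);
  const int n = query.nrow();
  NumericVector dist(n);
  IntegerVector idx(n);
  for (int i = 0; i < n; ++i) {
    double d2;
    int j;
    tree.query(query(i, 0), query(i, 1), query(i, 2), d2, j);
    dist[i] = std::sqrt(d2);
    idx[i] = j + 1;  // 1-based for R
  }
  return List::create(_["dist"] = dist, _["idx"] = idx);
}

// 8-connected component labelling of a binary matrix (BFS flood fill).
// Labels are assigned in row-major scan order starting at 1; 0 = background.

// [[Rcpp::export(name = ".label_components")]]
IntegerMatrix label_components(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        const int ci = q.front().first, cj = q.front().second;
        q.pop();
        for (int di = -1; di <= 1; ++di) {
          for (int dj = -1; dj <= 1; ++dj) {
            const int ni = ci + di, nj = cj + dj;
            if (ni < 0 || nj < 0 || ni >= nr || nj >= nc) continue;
            if (mask(ni, nj) && lab(ni, nj) == 0) {
              lab(ni, nj) = next;
              q.push(std::make_pair(ni, nj));
            }
          }
        }
      }
    }
  }
  return lab;
}
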