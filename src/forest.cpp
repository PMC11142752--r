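// Bootstrap CART forest for classification with Gini importance.
// Only the per-feature Mean Decrease Gini is needed downstream, so trees are
// not stored. Uses R's RNG (unif_rand) so results are reproducible under
// set.seed(). Ties in split search are broken by the first candidate
// encountered in the (random) mtry order; candidate thresholds are midpoints
// between consecutive distinct values.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

struct Node {
  std::vector<int> idx; // row indices of member samples
};

inline double gini(const std::vector<int> &counts, int n) {
  if (n == 0) return 0.0;
  double g = 1.0;
  for (int c : counts) {
    double p = static_cast<double>(c) / n;
    g -= p * p;
  }
  return g;
}

inline int rand_int(int n) { // uniform on 0..n-1
  int v = static_cast<int>(unif_rand() * n);
  return v >= n ? n - 1 : v;
}

} // namespace

// [[Rcpp::export(name = ".rf_gini_importance")]]
NumericVector rf_gini_importance(NumericMatrix X, IntegerVector y,
                                 int n_class, int n_trees, int mtry,
                                 int min_node) {
  const int n = X.nrow(), p = X.ncol();
  if (mtry < 1) mtry = 1;
  if (mtry > p) mtry = p;
  NumericVector importance(p);
  std::vector<int> feat_order(p);

  for (int t = 0; t < n_trees; ++t) {
    // bootstrap sample
    std::vector<Node> stack;
    Node root;
    root.idx.resize(n);
    for (int i = 0; i < n; ++i) root.idx[i] = rand_int(n);
    stack.push_back(std::move(root));

    while (!stack.empty()) {
      Node node = std::move(stack.back());
      stack.pop_back();
      const int n_node = node.idx.size();

      std::vector<int> counts(n_class, 0);
      for (int i : node.idx) counts[y[i]]++;
      const double g_parent = gini(counts, n_node);
      // min_node is a minimum-leaf-size constraint: every child must keep
      // at least min_node samples (limits memorization of stray samples,
      // which otherwise leaks Gini importance onto noise features)
      if (n_node < 2 * min_node || g_parent <= 0.0) continue;

      // draw mtry features without replacement (partial Fisher-Yates)
      for (int j = 0; j < p; ++j) feat_order[j] = j;
      for (int j = 0; j < mtry; ++j)
        std::swap(feat_order[j], feat_order[j + rand_int(p - j)]);

      double best_gain = 0.0, best_thresh = 0.0;
      int best_feat = -1;
      std::vector<std::pair<double, int>> vals(n_node);

      for (int f = 0; f < mtry; ++f) {
        const int j = feat_order[f];
        for (int i = 0; i < n_node; ++i)
          vals[i] = {X(node.idx[i], j), node.idx[i]};
        std::sort(vals.begin(), vals.end());
        if (vals.front().first == vals.back().first) continue;

        std::vector<int> left(n_class, 0), right(counts);
        int n_left = 0;
        for (int i = 0; i + 1 < n_node; ++i) {
          const int cls = y[vals[i].second];
          left[cls]++; right[cls]--; n_left++;
          if (vals[i].first == vals[i + 1].first) continue;
          const int n_right = n_node - n_left;
          if (n_left < min_node || n_right < min_node) continue;
          double gain = g_parent -
            (n_left * gini(left, n_left) + n_right * gini(right, n_right)) /
              n_node;
          if (gain > best_gain + 1e-12) {
            best_gain = gain;
            best_feat = j;
            best_thresh = 0.5 * (vals[i].first + vals[i + 1].first);
          }
        }
      }
      if (best_feat < 0) continue;

      importance[best_feat] += best_gain * n_node;
      Node lnode, rnode;
      for (int i : node.idx) {
        if (X(i, best_feat) <= best_thresh) lnode.idx.push_back(i);
        else rnode.idx.push_back(i);
      }
      if (!lnode.idx.empty() && !rnode.idx.empty()) {
        stack.push_back(std::move(lnode));
        stack.push_back(std::move(rnode));
      }
    }
  }
  for (int j = 0; j < p; ++j) importance[j] /= n_trees;
  return importance;
}
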