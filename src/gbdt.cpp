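#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Minimal deterministic gradient-boosted trees with logistic loss.
// Second-order (Newton) leaf weights and gain-based splits in the style of
// the mainstream boosted-tree libraries; no row/column subsampling, so the
// fit is a pure function of (X, y, hyperparameters) and feature order.

namespace {

struct Tree {
  std::vector<int> feature;      // -1 for leaf
  std::vector<double> threshold; // go left if x <= threshold
  std::vector<int> left, right;
  std::vector<double> value;     // leaf weight (already scaled by learning rate)
};

struct SplitInfo {
  bool found = false;
  int feature = -1;
  double threshold = 0.0;
  double gain = 0.0;
};

double leaf_objective(double G, double H, double lambda) {
  return (G * G) / (H + lambda);
}

SplitInfo best_split(const NumericMatrix& X,
                     const std::vector<double>& g,
                     const std::vector<double>& h,
                     const std::vector<int>& idx,
                     double lambda, double min_child_weight) {
  SplitInfo best;
  const int n = idx.size();
  double Gtot = 0.0, Htot = 0.0;
  for (int k = 0; k < n; ++k) { Gtot += g[idx[k]]; Htot += h[idx[k]]; }
  const double parent = leaf_objective(Gtot, Htot, lambda);

  std::vector<std::pair<double, int> > xs(n);
  for (int j = 0; j < X.ncol(); ++j) {
    for (int k = 0; k < n; ++k) xs[k] = std::make_pair(X(idx[k], j), idx[k]);
    std::sort(xs.begin(), xs.end());
    double GL = 0.0, HL = 0.0;
    for (int k = 0; k + 1 < n; ++k) {
      GL += g[xs[k].second];
      HL += h[xs[k].second];
      if (xs[k].first == xs[k + 1].first) continue; // not a valid cut point
      const double GR = Gtot - GL, HR = Htot - HL;
      if (HL < min_child_weight || HR < min_child_weight) continue;
      const double gain =
        0.5 * (leaf_objective(GL, HL, lambda) + leaf_objective(GR, HR, lambda) - parent);
      if (gain > best.gain + 1e-12) { // strict improvement; first feature wins ties
        best.found = true;
        best.feature = j;
        best.threshold = 0.5 * (xs[k].first + xs[k + 1].first);
        best.gain = gain;
      }
    }
  }
  return best;
}

int grow(Tree& tree, const NumericMatrix& X,
         const std::vector<double>& g, const std::vector<double>& h,
         const std::vector<int>& idx, int depth, int max_depth,
         double lambda, double lr, double min_child_weight,
         std::vector<double>& importance) {
  double G = 0.0, H = 0.0;
  for (size_t k = 0; k < idx.size(); ++k) { G += g[idx[k]]; H += h[idx[k]]; }

  const int node = tree.feature.size();
  tree.feature.push_back(-1);
  tree.threshold.push_back(0.0);
  tree.left.push_back(-1);
  tree.right.push_back(-1);
  tree.value.push_back(-lr * G / (H + lambda));

  if (depth >= max_depth || idx.size() < 2) return node;
  SplitInfo s = best_split(X, g, h, idx, lambda, min_child_weight);
  if (!s.found || s.gain <= 1e-8) return node;

  std::vector<int> li, ri;
  for (size_t k = 0; k < idx.size(); ++k) {
    if (X(idx[k], s.feature) <= s.threshold) li.push_back(idx[k]);
    else ri.push_back(idx[k]);
  }
  if (li.empty() || ri.empty()) return node;

  importance[s.feature] += s.gain;
  tree.feature[node] = s.feature;
  tree.threshold[node] = s.threshold;
  tree.left[node]  = grow(tree, X, g, h, li, depth + 1, max_depth, lambda, lr,
                          min_child_weight, importance);
  tree.right[node] = grow(tree, X, g, h, ri, depth + 1, max_depth, lambda, lr,
                          min_child_weight, importance);
  return node;
}

double tree_predict(const Tree& t, const NumericMatrix& X, int i) {
  int node = 0;
  while (t.feature[node] >= 0)
    node = (X(i, t.feature[node]) <= t.threshold[node]) ? t.left[node] : t.right[node];
  return t.value[node];
}

List tree_to_list(const Tree& t) {
  return List::create(_["feature"] = wrap(t.feature),
                      _["threshold"] = wrap(t.threshold),
                      _["left"] = wrap(t.left),
                      _["right"] = wrap(t.right),
                      _["value"] = wrap(t.value));
}

Tree tree_from_list(const List& l) {
  Tree t;
  t.feature = as<std::vector<int> >(l["feature"]);
  t.threshold = as<std::vector<double> >(l["threshold"]);
  t.left = as<std::vector<int> >(l["left"]);
  t.right = as<std::vector<int> >(l["right"]);
  t.value = as<std::vector<double> >(l["value"]);
  return t;
}

} // namespace

// [[Rcpp::export]]
List fit_gbdt_cpp(NumericMatrix X, NumericVector y, int n_trees, int max_depth,
                  double learning_rate, double lambda, double min_child_weight) {
  const int n = X.nrow(), p = X.ncol();
  if (y.size() != n) stop("length(y) must equal nrow(X)");

  double ybar = 0.0;
  for (int i = 0; i < n; ++i) ybar += y[i];
  ybar /= n;
  ybar = std::min(std::max(ybar, 1e-6), 1.0 - 1e-6);
  const double base = std::log(ybar / (1.0 - ybar));

  std::vector<double> margin(n, base), g(n), h(n), importance(p, 0.0);
  List trees(n_trees);
  for (int m = 0; m < n_trees; ++m) {
    for (int i = 0; i < n; ++i) {
      const double pr = 1.0 / (1.0 + std::exp(-margin[i]));
      g[i] = pr - y[i];
      h[i] = std::max(pr * (1.0 - pr), 1e-12);
    }
    Tree t;
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
    grow(t, X, g, h, idx, 0, max_depth, lambda, learning_rate,
         min_child_weight, importance);
    for (int i = 0; i < n; ++i) margin[i] += tree_predict(t, X, i);
    trees[m] = tree_to_list(t);
  }
  return List::create(_["trees"] = trees, _["base"] = base,
                      _["importance"] = wrap(importance));
}

// [[Rcpp::export]]
NumericVector predict_gbdt_cpp(List model, NumericMatrix X) {
  const int n = X.nrow();
  NumericVector margin(n, as<double>(model["base"]));
  List trees = model["trees"];
  for (int m = 0; m < trees.size(); ++m) {
    Tree t = tree_from_list(trees[m]);
    for (int i = 0; i < n; ++i) margin[i] += tree_predict(t, X, i);
  }
  return margin;
}
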