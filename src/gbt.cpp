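// Compact second-order gradient-boosted regression trees for binary
// logistic loss. Exact greedy splits, depth limit, L2 leaf regularization
// (lambda) and shrinkage (eta) as in standard boosting libraries.
// Trees are returned as plain numeric matrices so fitted models are
// ordinary R lists (serializable, no external pointers).
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct Tree {
  // column layout: feature (-1 leaf), threshold, left, right, value
  std::vector<double> feature, threshold, left, right, value;
  int add() {
    feature.push_back(-1); threshold.push_back(0);
    left.push_back(-1); right.push_back(-1); value.push_back(0);
    return static_cast<int>(feature.size()) - 1;
  }
};

int build(const NumericMatrix& X, const std::vector<double>& g,
          const std::vector<double>& h, std::vector<int>& idx, int depth,
          int max_depth, double lambda, double min_child_weight, double eta,
          Tree& tree) {
  const int node = tree.add();
  double G = 0, H = 0;
  for (int i : idx) { G += g[i]; H += h[i]; }

  double best_gain = 1e-12;
  int best_feat = -1;
  double best_thr = 0;
  const double parent_score = G * G / (H + lambda);

  if (depth < max_depth && idx.size() >= 2) {
    const int p = X.ncol();
    std::vector<int> ord;
    for (int f = 0; f < p; ++f) {
      ord = idx;
      std::sort(ord.begin(), ord.end(), [&](int a, int b) {
        return X(a, f) < X(b, f);
      });
      double GL = 0, HL = 0;
      for (size_t s = 0; s + 1 < ord.size(); ++s) {
        GL += g[ord[s]]; HL += h[ord[s]];
        const double xl = X(ord[s], f), xr = X(ord[s + 1], f);
        if (xr <= xl) continue;          // no split between ties
        const double GR = G - GL, HR = H - HL;
        if (HL < min_child_weight || HR < min_child_weight) continue;
        const double gain = 0.5 * (GL * GL / (HL + lambda) +
                                   GR * GR / (HR + lambda) - parent_score);
        if (gain > best_gain) {
          best_gain = gain; best_feat = f; best_thr = 0.5 * (xl + xr);
        }
      }
    }
  }

  if (best_feat < 0) {
    tree.value[node] = -eta * G / (H + lambda);
    return node;
  }
  std::vector<int> li, ri;
  for (int i : idx)
    (X(i, best_feat) < best_thr ? li : ri).push_back(i);
  tree.feature[node] = best_feat;
  tree.threshold[node] = best_thr;
  tree.left[node] = build(X, g, h, li, depth + 1, max_depth, lambda,
                          min_child_weight, eta, tree);
  tree.right[node] = build(X, g, h, ri, depth + 1, max_depth, lambda,
                           min_child_weight, eta, tree);
  return node;
}

NumericMatrix pack(const Tree& t) {
  const int m = static_cast<int>(t.feature.size());
  NumericMatrix out(m, 5);
  for (int i = 0; i < m; ++i) {
    out(i, 0) = t.feature[i]; out(i, 1) = t.threshold[i];
    out(i, 2) = t.left[i]; out(i, 3) = t.right[i]; out(i, 4) = t.value[i];
  }
  return out;
}

double tree_score(const NumericMatrix& t, const NumericMatrix& X, int row) {
  int node = 0;
  while (t(node, 0) >= 0) {
    const int f = static_cast<int>(t(node, 0));
    node = static_cast<int>(X(row, f) < t(node, 1) ? t(node, 2)
                                                   : t(node, 3));
  }
  return t(node, 4);
}

} // namespace

// [[Rcpp::export(name = ".gbt_fit_cpp")]]
List gbt_fit_cpp(NumericMatrix X, NumericVector y, int n_estimators,
                 int max_depth, double eta, double lambda,
                 double min_child_weight, double base_score) {
  const int n = X.nrow();
  std::vector<double> margin(n, base_score), g(n), h(n);
  std::vector<int> all(n);
  for (int i = 0; i < n; ++i) all[i] = i;
  List trees(n_estimators);
  for (int m = 0; m < n_estimators; ++m) {
    for (int i = 0; i < n; ++i) {
      const double p = 1.0 / (1.0 + std::exp(-margin[i]));
      g[i] = p - y[i];
      h[i] = std::max(p * (1.0 - p), 1e-16);
    }
    Tree tree;
    std::vector<int> idx = all;
    build(X, g, h, idx, 0, max_depth, lambda, min_child_weight, eta, tree);
    NumericMatrix packed = pack(tree);
    for (int i = 0; i < n; ++i) margin[i] += tree_score(packed, X, i);
    trees[m] = packed;
  }
  return List::create(_["trees"] = trees, _["base_score"] = base_score);
}

// [[Rcpp::export(name = ".gbt_margin_cpp")]]
NumericVector gbt_margin_cpp(List trees, double base_score,
                             NumericMatrix X) {
  const int n = X.nrow();
  NumericVector out(n, base_score);
  for (int m = 0; m < trees.size(); ++m) {
    NumericMatrix t = trees[m];
    for (int i = 0; i < n; ++i) out[i] += tree_score(t, X, i);
  }
  return out;
}
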