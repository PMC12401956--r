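// Tree ensembles used by the classifier zoo: a Gini CART random forest and
// second-order gradient-boosted trees with an L2-regularised objective.
// Both are exact greedy learners on dense numeric matrices; wrapper feature
// selection re-fits these thousands of times, hence C++.
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <random>
#include <vector>
using namespace Rcpp;

namespace {

struct FlatTree {
  // node arrays; leaf iff feature == -1, value = leaf output
  std::vector<int> feature;
  std::vector<double> threshold;
  std::vector<int> left;
  std::vector<int> right;
  std::vector<double> value;

  int new_node() {
    feature.push_back(-1);
    threshold.push_back(0.0);
    left.push_back(-1);
    right.push_back(-1);
    value.push_back(0.0);
    return (int)feature.size() - 1;
  }
};

inline double gini(double pos, double n) {
  if (n <= 0.0) return 0.0;
  const double p = pos / n;
  return 2.0 * p * (1.0 - p);
}

// ---- random forest -------------------------------------------------------

struct RfBuilder {
  const NumericMatrix& X;
  const double* xdat;  // column-major data pointer
  int n_rows;
  const IntegerVector& y;
  int d, mtry, min_split, max_depth;
  double n_total;
  std::mt19937& rng;
  std::vector<double>& importance;  // weighted impurity decrease, one slot per feature
  FlatTree tree;
  std::vector<int> feat_pool;

  RfBuilder(const NumericMatrix& X_, const IntegerVector& y_, int mtry_,
            int min_split_, int max_depth_, double n_total_, std::mt19937& rng_,
            std::vector<double>& imp_)
      : X(X_), xdat(X_.begin()), n_rows(X_.nrow()), y(y_), d(X_.ncol()),
        mtry(mtry_), min_split(min_split_), max_depth(max_depth_),
        n_total(n_total_), rng(rng_), importance(imp_) {
    feat_pool.resize(d);
    for (int j = 0; j < d; ++j) feat_pool[j] = j;
  }

  int build(std::vector<int>& idx, int depth) {
    const int node = tree.new_node();
    const int n = (int)idx.size();
    int pos = 0;
    for (int i : idx) pos += y[i];
    const double leaf_val = (double)pos / n;
    if (pos == 0 || pos == n || n < min_split || depth >= max_depth) {
      tree.value[node] = leaf_val;
      return node;
    }

    // candidate features: mtry sampled without replacement
    for (int j = d - 1; j > 0; --j) {
      std::uniform_int_distribution<int> u(0, j);
      std::swap(feat_pool[j], feat_pool[u(rng)]);
    }

    const double imp_parent = gini(pos, n);
    double best_gain = 1e-12;
    int best_f = -1;
    double best_thr = 0.0;
    std::vector<std::pair<double, int>> vals(n);

    for (int m = 0; m < mtry; ++m) {
      const int f = feat_pool[m];
      const double* xcol = xdat + (size_t)f * n_rows;
      for (int r = 0; r < n; ++r) vals[r] = {xcol[idx[r]], idx[r]};
      std::sort(vals.begin(), vals.end());
      double pos_l = 0.0;
      for (int r = 0; r < n - 1; ++r) {
        pos_l += y[vals[r].second];
        if (vals[r + 1].first <= vals[r].first) continue;  // tie: no cut here
        const double n_l = r + 1, n_r = n - n_l;
        const double child =
            (n_l * gini(pos_l, n_l) + n_r * gini(pos - pos_l, n_r)) / n;
        const double gain = imp_parent - child;
        if (gain > best_gain) {
          best_gain = gain;
          best_f = f;
          best_thr = 0.5 * (vals[r].first + vals[r + 1].first);
        }
      }
    }

    if (best_f < 0) {  // nothing separable among the sampled features
      tree.value[node] = leaf_val;
      return node;
    }

    importance[best_f] += ((double)n / n_total) * best_gain;

    std::vector<int> idx_l, idx_r;
    idx_l.reserve(n);
    idx_r.reserve(n);
    for (int i : idx) (X(i, best_f) <= best_thr ? idx_l : idx_r).push_back(i);

    tree.feature[node] = best_f;
    tree.threshold[node] = best_thr;
    tree.left[node] = build(idx_l, depth + 1);
    tree.right[node] = build(idx_r, depth + 1);
    return node;
  }
};

List flat_tree_to_list(const FlatTree& t) {
  return List::create(_["feature"] = wrap(t.feature),
                      _["threshold"] = wrap(t.threshold),
                      _["left"] = wrap(t.left), _["right"] = wrap(t.right),
                      _["value"] = wrap(t.value));
}

inline double tree_predict_row(const IntegerVector& feature,
                               const NumericVector& threshold,
                               const IntegerVector& left,
                               const IntegerVector& right,
                               const NumericVector& value,
                               const NumericMatrix& X, int row) {
  int node = 0;
  while (feature[node] >= 0)
    node = (X(row, feature[node]) <= threshold[node]) ? left[node] : right[node];
  return value[node];
}

}  // namespace

// [[Rcpp::export(name = ".rf_fit_cpp")]]
List rf_fit_cpp(NumericMatrix X, IntegerVector y, int n_trees, int mtry,
                int min_split, int max_depth, int seed) {
  const int n = X.nrow(), d = X.ncol();
  if (max_depth <= 0) max_depth = 1 << 30;
  if (mtry < 1) mtry = 1;
  if (mtry > d) mtry = d;
  std::mt19937 rng((uint32_t)seed);
  std::uniform_int_distribution<int> boot(0, n - 1);

  List trees(n_trees);
  std::vector<double> imp_total(d, 0.0);
  for (int t = 0; t < n_trees; ++t) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = boot(rng);
    std::vector<double> imp_tree(d, 0.0);
    RfBuilder b(X, y, mtry, min_split, max_depth, (double)n, rng, imp_tree);
    b.build(idx, 0);
    trees[t] = flat_tree_to_list(b.tree);
    double s = 0.0;
    for (double v : imp_tree) s += v;
    if (s > 0.0)
      for (int j = 0; j < d; ++j) imp_total[j] += imp_tree[j] / s;
  }
  double s = 0.0;
  for (double v : imp_total) s += v;
  NumericVector imp(d);
  for (int j = 0; j < d; ++j) imp[j] = (s > 0.0) ? imp_total[j] / s : 0.0;
  return List::create(_["trees"] = trees, _["importance"] = imp);
}

// [[Rcpp::export(name = ".forest_predict_cpp")]]
NumericVector forest_predict_cpp(List trees, NumericMatrix X, bool average) {
  const int n = X.nrow(), T = trees.size();
  NumericVector out(n, 0.0);
  for (int t = 0; t < T; ++t) {
    List tr = trees[t];
    IntegerVector feature = tr["feature"];
    NumericVector threshold = tr["threshold"];
    IntegerVector left = tr["left"], right = tr["right"];
    NumericVector value = tr["value"];
    for (int i = 0; i < n; ++i)
      out[i] += tree_predict_row(feature, threshold, left, right, value, X, i);
  }
  if (average && T > 0)
    for (int i = 0; i < n; ++i) out[i] /= T;
  return out;
}

// ---- gradient boosting ---------------------------------------------------

namespace {

struct GbtBuilder {
  const NumericMatrix& X;
  const std::vector<double>& g;
  const std::vector<double>& h;
  int d, max_depth;
  double lambda, gamma, min_child_weight;
  std::vector<double>& gain_by_feat;
  FlatTree tree;

  GbtBuilder(const NumericMatrix& X_, const std::vector<double>& g_,
             const std::vector<double>& h_, int max_depth_, double lambda_,
             double gamma_, double mcw_, std::vector<double>& gain_)
      : X(X_), g(g_), h(h_), d(X_.ncol()), max_depth(max_depth_),
        lambda(lambda_), gamma(gamma_), min_child_weight(mcw_),
        gain_by_feat(gain_) {}

  int build(std::vector<int>& idx, int depth) {
    const int node = tree.new_node();
    const int n = (int)idx.size();
    double G = 0.0, H = 0.0;
    for (int i : idx) {
      G += g[i];
      H += h[i];
    }
    const double leaf_w = -G / (H + lambda);
    if (depth >= max_depth || n < 2) {
      tree.value[node] = leaf_w;
      return node;
    }

    const double score_parent = G * G / (H + lambda);
    double best_gain = 1e-12;
    int best_f = -1;
    double best_thr = 0.0;
    std::vector<std::pair<double, int>> vals(n);

    const double* xdat = X.begin();
    const int n_rows = X.nrow();
    for (int f = 0; f < d; ++f) {
      const double* xcol = xdat + (size_t)f * n_rows;
      for (int r = 0; r < n; ++r) vals[r] = {xcol[idx[r]], idx[r]};
      std::sort(vals.begin(), vals.end());
      double GL = 0.0, HL = 0.0;
      for (int r = 0; r < n - 1; ++r) {
        GL += g[vals[r].second];
        HL += h[vals[r].second];
        if (vals[r + 1].first <= vals[r].first) continue;
        const double HR = H - HL, GR = G - GL;
        if (HL < min_child_weight || HR < min_child_weight) continue;
        const double gain = 0.5 * (GL * GL / (HL + lambda) +
                                   GR * GR / (HR + lambda) - score_parent) -
                            gamma;
        if (gain > best_gain) {
          best_gain = gain;
          best_f = f;
          best_thr = 0.5 * (vals[r].first + vals[r + 1].first);
        }
      }
    }

    if (best_f < 0) {
      tree.value[node] = leaf_w;
      return node;
    }
    gain_by_feat[best_f] += best_gain;

    std::vector<int> idx_l, idx_r;
    for (int i : idx) (X(i, best_f) <= best_thr ? idx_l : idx_r).push_back(i);
    tree.feature[node] = best_f;
    tree.threshold[node] = best_thr;
    tree.left[node] = build(idx_l, depth + 1);
    tree.right[node] = build(idx_r, depth + 1);
    return node;
  }
};

}  // namespace

// [[Rcpp::export(name = ".gbt_fit_cpp")]]
List gbt_fit_cpp(NumericMatrix X, IntegerVector y, int n_rounds, double eta,
                 int max_depth, double lambda, double gamma,
                 double min_child_weight, double base_score) {
  const int n = X.nrow(), d = X.ncol();
  const double base_margin = std::log(base_score / (1.0 - base_score));
  std::vector<double> margin(n, base_margin), g(n), h(n);
  std::vector<double> gain_by_feat(d, 0.0);
  List trees(n_rounds);

  for (int t = 0; t < n_rounds; ++t) {
    for (int i = 0; i < n; ++i) {
      const double p = 1.0 / (1.0 + std::exp(-margin[i]));
      g[i] = p - y[i];
      h[i] = std::max(p * (1.0 - p), 1e-16);
    }
    GbtBuilder b(X, g, h, max_depth, lambda, gamma, min_child_weight,
                 gain_by_feat);
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
    b.build(idx, 0);
    trees[t] = flat_tree_to_list(b.tree);
    const FlatTree& tr = b.tree;
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (tr.feature[node] >= 0)
        node = (X(i, tr.feature[node]) <= tr.threshold[node]) ? tr.left[node]
                                                              : tr.right[node];
      margin[i] += eta * tr.value[node];
    }
  }

  double s = 0.0;
  for (double v : gain_by_feat) s += v;
  NumericVector imp(d);
  for (int j = 0; j < d; ++j) imp[j] = (s > 0.0) ? gain_by_feat[j] / s : 0.0;
  return List::create(_["trees"] = trees, _["importance"] = imp,
                      _["base_margin"] = base_margin, _["eta"] = eta);
}

// [[Rcpp::export(name = ".gbt_predict_cpp")]]
NumericVector gbt_predict_cpp(List model, NumericMatrix X) {
  List trees = model["trees"];
  const double base_margin = as<double>(model["base_margin"]);
  const double eta = as<double>(model["eta"]);
  NumericVector m = forest_predict_cpp(trees, X, false);
  const int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = 1.0 / (1.0 + std::exp(-(base_margin + eta * m[i])));
  return out;
}
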