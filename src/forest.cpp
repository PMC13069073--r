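// Classification tree ensembles: CART forests (bootstrap/mtry), extremely
// randomized trees (random thresholds, no bootstrap) and SAMME AdaBoost on
// depth-1 stumps. Uses R's RNG throughout so set.seed() governs every fit.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct TreeBuf {
  std::vector<int> feature;        // -1 for leaf
  std::vector<double> threshold;
  std::vector<int> left, right;
  std::vector<double> value;       // n_nodes * K class proportions
};

class Grower {
public:
  const NumericMatrix &X;
  const IntegerVector &y;          // 0..K-1
  const std::vector<double> &w;
  int K, mtry, min_leaf, max_depth;
  bool extra;
  std::vector<double> &imp;        // length p, accumulated impurity decrease
  TreeBuf buf;

  Grower(const NumericMatrix &X_, const IntegerVector &y_,
         const std::vector<double> &w_, int K_, int mtry_, int min_leaf_,
         int max_depth_, bool extra_, std::vector<double> &imp_)
      : X(X_), y(y_), w(w_), K(K_), mtry(mtry_), min_leaf(min_leaf_),
        max_depth(max_depth_), extra(extra_), imp(imp_) {}

  int new_node() {
    buf.feature.push_back(-1);
    buf.threshold.push_back(0.0);
    buf.left.push_back(-1);
    buf.right.push_back(-1);
    for (int k = 0; k < K; ++k) buf.value.push_back(0.0);
    return (int)buf.feature.size() - 1;
  }

  static double gini(const std::vector<double> &cnt, double W) {
    if (W <= 0) return 0.0;
    double s = 0.0;
    for (double c : cnt) s += (c / W) * (c / W);
    return 1.0 - s;
  }

  int build(std::vector<int> &idx, int depth) {
    int node = new_node();
    std::vector<double> cnt(K, 0.0);
    double W = 0.0;
    for (int i : idx) { cnt[y[i]] += w[i]; W += w[i]; }
    for (int k = 0; k < K; ++k)
      buf.value[(size_t)node * K + k] = W > 0 ? cnt[k] / W : 1.0 / K;
    double g = gini(cnt, W);
    int n = (int)idx.size();
    if (depth >= max_depth || n < 2 * min_leaf || g <= 0.0) return node;

    // sample candidate features without replacement
    int p = X.ncol();
    int m = std::min(mtry, p);
    std::vector<int> feats(p);
    for (int j = 0; j < p; ++j) feats[j] = j;
    for (int j = 0; j < m; ++j) {
      int r = j + (int)(unif_rand() * (p - j));
      if (r >= p) r = p - 1;
      std::swap(feats[j], feats[r]);
    }

    double best_score = -1.0;  // impurity decrease
    int best_f = -1;
    double best_thr = 0.0;
    std::vector<std::pair<double, int> > pairs(n);

    for (int jj = 0; jj < m; ++jj) {
      int f = feats[jj];
      if (extra) {
        double lo = R_PosInf, hi = R_NegInf;
        for (int i : idx) {
          double v = X(i, f);
          if (v < lo) lo = v;
          if (v > hi) hi = v;
        }
        if (!(hi > lo)) continue;
        double thr = lo + unif_rand() * (hi - lo);
        std::vector<double> cl(K, 0.0);
        double WL = 0.0;
        int nl = 0;
        for (int i : idx) {
          if (X(i, f) <= thr) { cl[y[i]] += w[i]; WL += w[i]; ++nl; }
        }
        if (nl < min_leaf || n - nl < min_leaf) continue;
        std::vector<double> cr(K);
        for (int k = 0; k < K; ++k) cr[k] = cnt[k] - cl[k];
        double WR = W - WL;
        double score = W * g - WL * gini(cl, WL) - WR * gini(cr, WR);
        if (score > best_score) { best_score = score; best_f = f; best_thr = thr; }
      } else {
        for (int i = 0; i < n; ++i) pairs[i] = std::make_pair(X(idx[i], f), idx[i]);
        std::sort(pairs.begin(), pairs.end());
        if (!(pairs[n - 1].first > pairs[0].first)) continue;
        std::vector<double> cl(K, 0.0);
        double WL = 0.0;
        for (int i = 0; i + 1 < n; ++i) {
          int s = pairs[i].second;
          cl[y[s]] += w[s];
          WL += w[s];
          if (pairs[i + 1].first <= pairs[i].first) continue;  // tie, no cut here
          int nl = i + 1;
          if (nl < min_leaf || n - nl < min_leaf) continue;
          std::vector<double> cr(K);
          for (int k = 0; k < K; ++k) cr[k] = cnt[k] - cl[k];
          double WR = W - WL;
          double score = W * g - WL * gini(cl, WL) - WR * gini(cr, WR);
          if (score > best_score) {
            best_score = score;
            best_f = f;
            best_thr = 0.5 * (pairs[i].first + pairs[i + 1].first);
          }
        }
      }
    }
    if (best_f < 0 || best_score <= 1e-12) return node;

    std::vector<int> lidx, ridx;
    lidx.reserve(n);
    ridx.reserve(n);
    for (int i : idx) {
      if (X(i, best_f) <= best_thr) lidx.push_back(i); else ridx.push_back(i);
    }
    if (lidx.empty() || ridx.empty()) return node;
    imp[best_f] += best_score;
    buf.feature[node] = best_f;
    buf.threshold[node] = best_thr;
    // free idx memory before recursing
    std::vector<int>().swap(idx);
    buf.left[node] = build(lidx, depth + 1);
    buf.right[node] = build(ridx, depth + 1);
    return node;
  }
};

List tree_to_list(const TreeBuf &b) {
  return List::create(_["feature"] = wrap(b.feature),
                      _["threshold"] = wrap(b.threshold),
                      _["left"] = wrap(b.left), _["right"] = wrap(b.right),
                      _["value"] = wrap(b.value));
}

void predict_tree(const List &tree, const NumericMatrix &X, int K,
                  NumericMatrix &out, double scale) {
  IntegerVector feature = tree["feature"];
  NumericVector threshold = tree["threshold"];
  IntegerVector left = tree["left"], right = tree["right"];
  NumericVector value = tree["value"];
  int n = X.nrow();
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] >= 0)
      node = X(i, feature[node]) <= threshold[node] ? left[node] : right[node];
    for (int k = 0; k < K; ++k) out(i, k) += scale * value[(size_t)node * K + k];
  }
}

}  // namespace

// [[Rcpp::export(name = ".cpp_forest_fit")]]
List cpp_forest_fit(NumericMatrix X, IntegerVector y, int K, int n_trees,
                    int mtry, int min_leaf, int max_depth, bool bootstrap,
                    bool extra) {
  int n = X.nrow(), p = X.ncol();
  std::vector<double> w(n, 1.0);
  std::vector<double> imp(p, 0.0);
  List trees(n_trees);
  RNGScope scope;
  for (int t = 0; t < n_trees; ++t) {
    std::vector<int> idx(n);
    if (bootstrap) {
      for (int i = 0; i < n; ++i) {
        int r = (int)(unif_rand() * n);
        idx[i] = r >= n ? n - 1 : r;
      }
    } else {
      for (int i = 0; i < n; ++i) idx[i] = i;
    }
    Grower g(X, y, w, K, mtry, min_leaf, max_depth, extra, imp);
    g.build(idx, 0);
    trees[t] = tree_to_list(g.buf);
  }
  double tot = 0.0;
  for (double v : imp) tot += v;
  NumericVector importance(p);
  for (int j = 0; j < p; ++j) importance[j] = tot > 0 ? imp[j] / tot : 0.0;
  return List::create(_["trees"] = trees, _["importance"] = importance,
                      _["K"] = K);
}

// [[Rcpp::export(name = ".cpp_forest_predict")]]
NumericMatrix cpp_forest_predict(List model, NumericMatrix X) {
  int K = as<int>(model["K"]);
  List trees = model["trees"];
  int T = trees.size(), n = X.nrow();
  NumericMatrix out(n, K);
  for (int t = 0; t < T; ++t) predict_tree(trees[t], X, K, out, 1.0 / T);
  return out;
}

// [[Rcpp::export(name = ".cpp_ada_fit")]]
List cpp_ada_fit(NumericMatrix X, IntegerVector y, int K, int n_stumps) {
  int n = X.nrow(), p = X.ncol();
  std::vector<double> w(n, 1.0 / n);
  std::vector<double> imp(p, 0.0);
  std::vector<double> alphas;
  List stumps(n_stumps);
  int used = 0;
  RNGScope scope;
  for (int m = 0; m < n_stumps; ++m) {
    std::vector<double> imp_local(p, 0.0);
    Grower g(X, y, w, K, p, 1, 1, false, imp_local);
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
    g.build(idx, 0);
    if (g.buf.feature[0] < 0) break;  // no usable split left
    // stump class predictions on training data
    std::vector<int> pred(n);
    for (int i = 0; i < n; ++i) {
      int node = X(i, g.buf.feature[0]) <= g.buf.threshold[0] ? g.buf.left[0]
                                                              : g.buf.right[0];
      int best = 0;
      double bv = -1.0;
      for (int k = 0; k < K; ++k) {
        double v = g.buf.value[(size_t)node * K + k];
        if (v > bv) { bv = v; best = k; }
      }
      pred[i] = best;
    }
    double err = 0.0;
    for (int i = 0; i < n; ++i) if (pred[i] != y[i]) err += w[i];
    if (err >= 1.0 - 1.0 / K) break;  // worse than chance: stop (SAMME)
    double alpha;
    bool perfect = err <= 1e-12;
    if (perfect) alpha = std::log(1e10) + std::log((double)K - 1.0);
    else alpha = std::log((1.0 - err) / err) + std::log((double)K - 1.0);
    stumps[used] = tree_to_list(g.buf);
    alphas.push_back(alpha);
    imp[g.buf.feature[0]] += alpha;
    ++used;
    if (perfect) break;
    double tot = 0.0;
    for (int i = 0; i < n; ++i) {
      if (pred[i] != y[i]) w[i] *= std::exp(alpha);
      tot += w[i];
    }
    for (int i = 0; i < n; ++i) w[i] /= tot;
  }
  List kept(used);
  NumericVector av(used);
  for (int m = 0; m < used; ++m) { kept[m] = stumps[m]; av[m] = alphas[m]; }
  double tot = 0.0;
  for (double v : imp) tot += v;
  NumericVector importance(p);
  for (int j = 0; j < p; ++j) importance[j] = tot > 0 ? imp[j] / tot : 0.0;
  return List::create(_["stumps"] = kept, _["alpha"] = av,
                      _["importance"] = importance, _["K"] = K);
}

// [[Rcpp::export(name = ".cpp_ada_predict")]]
NumericMatrix cpp_ada_predict(List model, NumericMatrix X) {
  int K = as<int>(model["K"]);
  List stumps = model["stumps"];
  NumericVector alpha = model["alpha"];
  int M = stumps.size(), n = X.nrow();
  NumericMatrix votes(n, K);
  for (int m = 0; m < M; ++m) {
    List st = stumps[m];
    IntegerVector feature = st["feature"];
    NumericVector threshold = st["threshold"];
    IntegerVector left = st["left"], right = st["right"];
    NumericVector value = st["value"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feature[node] >= 0)
        node = X(i, feature[node]) <= threshold[node] ? left[node] : right[node];
      int best = 0;
      double bv = -1.0;
      for (int k = 0; k < K; ++k) {
        double v = value[(size_t)node * K + k];
        if (v > bv) { bv = v; best = k; }
      }
      votes(i, best) += alpha[m];
    }
  }
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int k = 0; k < K; ++k) s += votes(i, k);
    if (s <= 0) {
      for (int k = 0; k < K; ++k) votes(i, k) = 1.0 / K;
    } else {
      for (int k = 0; k < K; ++k) votes(i, k) /= s;
    }
  }
  return votes;
}
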