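// Regression random forest: CART trees on bootstrap samples with a
// random feature subset (mtry) per split and a minimum leaf size.
// Uses R's RNG so forests are deterministic under set.seed() from R.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Tree {
  std::vector<int> feature;      // split feature (0-based), -1 for leaf
  std::vector<double> threshold;
  std::vector<int> left, right;  // child node ids, -1 for leaf
  std::vector<double> value;     // leaf prediction (node mean)
};

int sample_int(int n) {  // uniform on 0..n-1 via R RNG
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

void grow(Tree& tree, const NumericMatrix& X, const NumericVector& y,
          std::vector<int>& idx, int lo, int hi, int mtry, int min_leaf,
          std::vector<int>& feat_pool, int node_id) {
  const int n = hi - lo;
  double sum = 0.0, sum2 = 0.0;
  for (int i = lo; i < hi; ++i) { sum += y[idx[i]]; sum2 += y[idx[i]] * y[idx[i]]; }
  const double mean = sum / n;
  tree.value[node_id] = mean;
  const double sse = sum2 - sum * sum / n;
  if (n < 2 * min_leaf || sse <= 1e-12) return;  // leaf

  // draw mtry distinct features (partial Fisher-Yates on the pool)
  const int p = feat_pool.size();
  const int m = std::min(mtry, p);
  for (int i = 0; i < m; ++i) {
    int j = i + sample_int(p - i);
    std::swap(feat_pool[i], feat_pool[j]);
  }

  double best_gain = 0.0, best_thr = 0.0;
  int best_feat = -1;
  std::vector<int> ord(idx.begin() + lo, idx.begin() + hi);
  std::vector<int> best_ord;
  int best_nl = 0;
  for (int fi = 0; fi < m; ++fi) {
    const int f = feat_pool[fi];
    std::sort(ord.begin(), ord.end(), [&](int a, int b) {
      return X(a, f) < X(b, f);
    });
    double lsum = 0.0;
    for (int i = 0; i < n - 1; ++i) {
      lsum += y[ord[i]];
      const int nl = i + 1, nr = n - nl;
      if (nl < min_leaf || nr < min_leaf) continue;
      if (X(ord[i], f) == X(ord[i + 1], f)) continue;  // no real split here
      const double rsum = sum - lsum;
      const double gain = lsum * lsum / nl + rsum * rsum / nr - sum * sum / n;
      if (gain > best_gain + 1e-12) {
        best_gain = gain;
        best_feat = f;
        best_thr = 0.5 * (X(ord[i], f) + X(ord[i + 1], f));
        best_ord = ord;
        best_nl = nl;
      }
    }
  }
  if (best_feat < 0) return;  // leaf: no split improves SSE

  std::copy(best_ord.begin(), best_ord.end(), idx.begin() + lo);
  const int mid = lo + best_nl;
  const int left_id = tree.feature.size();
  const int right_id = left_id + 1;
  for (int r = 0; r < 2; ++r) {
    tree.feature.push_back(-1);
    tree.threshold.push_back(0.0);
    tree.left.push_back(-1);
    tree.right.push_back(-1);
    tree.value.push_back(0.0);
  }
  tree.feature[node_id] = best_feat;
  tree.threshold[node_id] = best_thr;
  tree.left[node_id] = left_id;
  tree.right[node_id] = right_id;
  grow(tree, X, y, idx, lo, mid, mtry, min_leaf, feat_pool, left_id);
  grow(tree, X, y, idx, mid, hi, mtry, min_leaf, feat_pool, right_id);
}

}  // namespace

// [[Rcpp::export]]
List rf_fit_cpp(NumericMatrix X, NumericVector y, int n_trees, int mtry,
                int min_leaf) {
  const int n = X.nrow(), p = X.ncol();
  List forest(n_trees);
  for (int t = 0; t < n_trees; ++t) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = sample_int(n);  // bootstrap
    Tree tree;
    tree.feature.assign(1, -1);
    tree.threshold.assign(1, 0.0);
    tree.left.assign(1, -1);
    tree.right.assign(1, -1);
    tree.value.assign(1, 0.0);
    std::vector<int> feat_pool(p);
    for (int f = 0; f < p; ++f) feat_pool[f] = f;
    grow(tree, X, y, idx, 0, n, mtry, min_leaf, feat_pool, 0);
    forest[t] = List::create(
        Named("feature") = IntegerVector(tree.feature.begin(), tree.feature.end()),
        Named("threshold") = NumericVector(tree.threshold.begin(), tree.threshold.end()),
        Named("left") = IntegerVector(tree.left.begin(), tree.left.end()),
        Named("right") = IntegerVector(tree.right.begin(), tree.right.end()),
        Named("value") = NumericVector(tree.value.begin(), tree.value.end()));
  }
  return forest;
}

// [[Rcpp::export]]
NumericVector rf_predict_cpp(List forest, NumericMatrix X) {
  const int n = X.nrow(), T = forest.size();
  NumericVector out(n);
  for (int t = 0; t < T; ++t) {
    List tr = forest[t];
    IntegerVector feature = tr["feature"];
    NumericVector threshold = tr["threshold"];
    IntegerVector left = tr["left"], right = tr["right"];
    NumericVector value = tr["value"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feature[node] >= 0) {
        node = X(i, feature[node]) <= threshold[node] ? left[node]
                                                      : right[node];
      }
      out[i] += value[node];
    }
  }
  return out / (double)T;
}
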