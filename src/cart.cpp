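#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Classification trees (binary 0/1 labels, Gini impurity) with per-node
// random feature subsampling, the building block for the bagged forest.
// Trees are stored as flat parallel arrays; feat == -1 marks a leaf.
// All randomness (feature subsampling, bootstrap) goes through R's RNG so
// results are reproducible under set.seed().

struct TreeBuf {
  std::vector<int> feat;
  std::vector<double> thr;
  std::vector<int> left, right;
  std::vector<double> prob;  // P(y = 1) among training rows in the node
};

static int grow_node(const NumericMatrix& X, const IntegerVector& y,
                     std::vector<int>& idx, int lo, int hi,
                     int mtry, int min_node, int depth, int max_depth,
                     TreeBuf& T) {
  const int n = hi - lo;
  int pos = 0;
  for (int i = lo; i < hi; ++i) pos += y[idx[i]];
  const int node = (int)T.feat.size();
  T.feat.push_back(-1);
  T.thr.push_back(0.0);
  T.left.push_back(-1);
  T.right.push_back(-1);
  T.prob.push_back(n > 0 ? (double)pos / n : 0.5);
  if (n < 2 * min_node || pos == 0 || pos == n || depth >= max_depth)
    return node;

  const int p = X.ncol();
  const int m = std::min(mtry, p);
  // partial Fisher-Yates draw of m candidate features
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  for (int j = 0; j < m; ++j) {
    int k = j + (int)(unif_rand() * (p - j));
    if (k >= p) k = p - 1;
    std::swap(feats[j], feats[k]);
  }

  // parent impurity in the "n * gini / 2" form so gains are comparable
  const double parent = (double)pos * (n - pos) / n;
  double best_gain = 0.0, best_thr = 0.0;
  int best_f = -1;
  std::vector<std::pair<double, int> > v(n);
  for (int jj = 0; jj < m; ++jj) {
    const int f = feats[jj];
    for (int i = 0; i < n; ++i)
      v[i] = std::make_pair(X(idx[lo + i], f), (int)y[idx[lo + i]]);
    std::sort(v.begin(), v.end());
    int lp = 0;
    for (int i = 0; i < n - 1; ++i) {
      lp += v[i].second;
      if (v[i].first == v[i + 1].first) continue;  // no split between ties
      const int nl = i + 1, nr = n - nl, rp = pos - lp;
      if (nl < min_node || nr < min_node) continue;
      const double child =
          (double)lp * (nl - lp) / nl + (double)rp * (nr - rp) / nr;
      const double gain = parent - child;
      if (gain > best_gain + 1e-12) {
        best_gain = gain;
        best_f = f;
        best_thr = 0.5 * (v[i].first + v[i + 1].first);
      }
    }
  }
  if (best_f < 0) return node;

  int mid = lo;
  for (int i = lo; i < hi; ++i)
    if (X(idx[i], best_f) <= best_thr) std::swap(idx[mid++], idx[i]);
  if (mid == lo || mid == hi) return node;  // numerically degenerate split

  T.feat[node] = best_f;
  T.thr[node] = best_thr;
  const int L = grow_node(X, y, idx, lo, mid, mtry, min_node, depth + 1,
                          max_depth, T);
  const int R = grow_node(X, y, idx, mid, hi, mtry, min_node, depth + 1,
                          max_depth, T);
  T.left[node] = L;
  T.right[node] = R;
  return node;
}

static List tree_to_list(const TreeBuf& T) {
  return List::create(_["feat"] = wrap(T.feat), _["thr"] = wrap(T.thr),
                      _["left"] = wrap(T.left), _["right"] = wrap(T.right),
                      _["prob"] = wrap(T.prob));
}

// [[Rcpp::export(name = ".cart_grow")]]
List cart_grow(NumericMatrix X, IntegerVector y, int mtry, int min_node,
               int max_depth) {
  const int n = X.nrow();
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  TreeBuf T;
  grow_node(X, y, idx, 0, n, mtry, min_node, 0, max_depth, T);
  return tree_to_list(T);
}

// [[Rcpp::export(name = ".cart_forest")]]
List cart_forest(NumericMatrix X, IntegerVector y, int ntree, int mtry,
                 int min_node, int max_depth, double sample_frac) {
  const int n = X.nrow();
  const int nb = std::max(1, (int)(sample_frac * n + 0.5));
  List trees(ntree);
  for (int t = 0; t < ntree; ++t) {
    // bootstrap sample (with replacement)
    NumericMatrix Xb(nb, X.ncol());
    IntegerVector yb(nb);
    for (int i = 0; i < nb; ++i) {
      int k = (int)(unif_rand() * n);
      if (k >= n) k = n - 1;
      Xb(i, _) = X(k, _);
      yb[i] = y[k];
    }
    std::vector<int> idx(nb);
    for (int i = 0; i < nb; ++i) idx[i] = i;
    TreeBuf T;
    grow_node(Xb, yb, idx, 0, nb, mtry, min_node, 0, max_depth, T);
    trees[t] = tree_to_list(T);
  }
  return trees;
}

static double tree_pred_row(const IntegerVector& feat, const NumericVector& thr,
                            const IntegerVector& left,
                            const IntegerVector& right,
                            const NumericVector& prob, const NumericMatrix& X,
                            int row) {
  int node = 0;
  while (feat[node] >= 0) {
    node = (X(row, feat[node]) <= thr[node]) ? left[node] : right[node];
  }
  return prob[node];
}

// [[Rcpp::export(name = ".cart_predict")]]
NumericVector cart_predict(List trees, NumericMatrix X) {
  const int n = X.nrow(), nt = trees.size();
  NumericVector out(n, 0.0);
  for (int t = 0; t < nt; ++t) {
    List tr = trees[t];
    IntegerVector feat = tr["feat"], left = tr["left"], right = tr["right"];
    NumericVector thr = tr["thr"], prob = tr["prob"];
    for (int i = 0; i < n; ++i)
      out[i] += tree_pred_row(feat, thr, left, right, prob, X, i);
  }
  return out / (double)nt;
}
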