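// Exact greedy regression tree on gradient/hessian pairs, shared by the
// random-forest (g = -y, h = 1, lambda = 0 -> variance-reduction splits,
// leaf = mean(y)) and boosted-tree (logistic g/h, lambda > 0 -> Newton leaf)
// learners. Per-node feature subsampling draws from R's RNG stream.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

struct TreeAcc {
  std::vector<int> feature, left, right;
  std::vector<double> threshold, value;
};

static int grow(const NumericMatrix& X, const NumericVector& g,
                const NumericVector& h, std::vector<int>& rows,
                int depth, int max_depth, double min_child_weight,
                int mtry, double lambda, double min_gain, TreeAcc& T) {
  double G = 0.0, H = 0.0;
  for (int r : rows) { G += g[r]; H += h[r]; }
  int node = (int) T.feature.size();
  T.feature.push_back(-1);
  T.threshold.push_back(0.0);
  T.left.push_back(-1);
  T.right.push_back(-1);
  T.value.push_back(-G / (H + lambda));
  if (depth >= max_depth || (int) rows.size() < 2) return node;

  int p = X.ncol();
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  // partial Fisher-Yates for the mtry candidate features
  int ncand = std::min(mtry, p);
  for (int j = 0; j < ncand; ++j) {
    int k = j + (int) (unif_rand() * (p - j));
    std::swap(feats[j], feats[k]);
  }

  double parent_score = G * G / (H + lambda);
  double best_gain = min_gain;
  int best_f = -1;
  double best_thr = 0.0;
  std::vector<int> order(rows);
  for (int jj = 0; jj < ncand; ++jj) {
    int f = feats[jj];
    std::sort(order.begin(), order.end(), [&](int a, int b) {
      return X(a, f) < X(b, f);
    });
    double GL = 0.0, HL = 0.0;
    for (size_t i = 0; i + 1 < order.size(); ++i) {
      int r = order[i];
      GL += g[r]; HL += h[r];
      double x0 = X(r, f), x1 = X(order[i + 1], f);
      if (x1 <= x0) continue;                    // no valid cut between ties
      double GR = G - GL, HR = H - HL;
      if (HL < min_child_weight || HR < min_child_weight) continue;
      double gain = GL * GL / (HL + lambda) + GR * GR / (HR + lambda)
                    - parent_score;
      if (gain > best_gain) {
        best_gain = gain;
        best_f = f;
        best_thr = 0.5 * (x0 + x1);
      }
    }
  }
  if (best_f < 0) return node;

  std::vector<int> lrows, rrows;
  for (int r : rows)
    (X(r, best_f) <= best_thr ? lrows : rrows).push_back(r);
  if (lrows.empty() || rrows.empty()) return node;
  T.feature[node] = best_f;
  T.threshold[node] = best_thr;
  int l = grow(X, g, h, lrows, depth + 1, max_depth, min_child_weight,
               mtry, lambda, min_gain, T);
  int r = grow(X, g, h, rrows, depth + 1, max_depth, min_child_weight,
               mtry, lambda, min_gain, T);
  T.left[node] = l;
  T.right[node] = r;
  return node;
}

// [[Rcpp::export]]
List cpp_grow_tree(NumericMatrix X, NumericVector g, NumericVector h,
                   IntegerVector rows, int max_depth, double min_child_weight,
                   int mtry, double lambda, double min_gain) {
  TreeAcc T;
  std::vector<int> rv(rows.begin(), rows.end());
  grow(X, g, h, rv, 0, max_depth, min_child_weight, mtry, lambda, min_gain, T);
  return List::create(_["feature"] = wrap(T.feature),
                      _["threshold"] = wrap(T.threshold),
                      _["left"] = wrap(T.left),
                      _["right"] = wrap(T.right),
                      _["value"] = wrap(T.value));
}

// [[Rcpp::export]]
NumericVector cpp_predict_tree(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"], left = tree["left"],
                right = tree["right"];
  NumericVector threshold = tree["threshold"], value = tree["value"];
  int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] >= 0)
      node = X(i, feature[node]) <= threshold[node] ? left[node] : right[node];
    out[i] = value[node];
  }
  return out;
}
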