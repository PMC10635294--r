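#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <random>
#include <cmath>
using namespace Rcpp;

// Depth-limited least-squares regression tree used as the base learner of
// the multinomial gradient-boosting classifier.  Splits are exact greedy
// over a per-node random feature subset (max_features); leaf values are the
// one-step Newton update sum(g)/sum(h) scaled by (K-1)/K as in classical
// multiclass deviance boosting.

struct Node {
  int feature = -1;
  double threshold = 0.0;
  int left = -1, right = -1;
  double value = 0.0;
};

static void grow(std::vector<Node>& nodes, int node_id,
                 const NumericMatrix& X,
                 const std::vector<double>& g, const std::vector<double>& h,
                 std::vector<int>& rows, int depth,
                 int max_depth, int min_split, int max_features,
                 double leaf_scale, std::mt19937& rng) {
  int n = (int)rows.size();
  double gsum = 0.0, hsum = 0.0;
  for (int r : rows) { gsum += g[r]; hsum += h[r]; }

  bool make_leaf = (depth >= max_depth) || (n < min_split);
  int best_f = -1; double best_gain = 0.0, best_thr = 0.0;
  std::vector<int> left_rows, right_rows;

  if (!make_leaf) {
    int p = X.ncol();
    std::vector<int> feats(p);
    for (int i = 0; i < p; ++i) feats[i] = i;
    std::shuffle(feats.begin(), feats.end(), rng);
    int nf = std::min(p, max_features);
    double base = gsum * gsum / n;

    std::vector<std::pair<double, int> > vals(n);
    for (int fi = 0; fi < nf; ++fi) {
      int f = feats[fi];
      for (int i = 0; i < n; ++i) vals[i] = { X(rows[i], f), rows[i] };
      std::sort(vals.begin(), vals.end());
      double lsum = 0.0;
      for (int i = 0; i < n - 1; ++i) {
        lsum += g[vals[i].second];
        if (vals[i + 1].first <= vals[i].first + 1e-12) continue;
        int nl = i + 1, nr = n - nl;
        double gain = lsum * lsum / nl +
                      (gsum - lsum) * (gsum - lsum) / nr - base;
        if (gain > best_gain + 1e-12) {
          best_gain = gain; best_f = f;
          best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
        }
      }
    }
    if (best_f < 0) make_leaf = true;
  }

  if (make_leaf) {
    nodes[node_id].feature = -1;
    nodes[node_id].value = leaf_scale * gsum / std::max(hsum, 1e-10);
    return;
  }
  for (int r : rows) {
    if (X(r, best_f) <= best_thr) left_rows.push_back(r);
    else right_rows.push_back(r);
  }
  nodes[node_id].feature = best_f;
  nodes[node_id].threshold = best_thr;
  int li = (int)nodes.size(); nodes.push_back(Node());
  int ri = (int)nodes.size(); nodes.push_back(Node());
  nodes[node_id].left = li; nodes[node_id].right = ri;
  rows.clear(); rows.shrink_to_fit();
  grow(nodes, li, X, g, h, left_rows, depth + 1, max_depth, min_split,
       max_features, leaf_scale, rng);
  grow(nodes, ri, X, g, h, right_rows, depth + 1, max_depth, min_split,
       max_features, leaf_scale, rng);
}

// [[Rcpp::export]]
List fit_tree_cpp(NumericMatrix X, NumericVector g, NumericVector h,
                  IntegerVector rows, int max_depth, int min_split,
                  int max_features, double leaf_scale, int seed) {
  std::mt19937 rng((unsigned)seed);
  std::vector<double> gv(g.begin(), g.end()), hv(h.begin(), h.end());
  std::vector<int> rv(rows.size());
  for (int i = 0; i < rows.size(); ++i) rv[i] = rows[i] - 1;
  std::vector<Node> nodes;
  nodes.push_back(Node());
  grow(nodes, 0, X, gv, hv, rv, 0, max_depth, min_split, max_features,
       leaf_scale, rng);
  int m = (int)nodes.size();
  IntegerVector feature(m), left(m), right(m);
  NumericVector threshold(m), value(m);
  for (int i = 0; i < m; ++i) {
    feature[i] = nodes[i].feature; threshold[i] = nodes[i].threshold;
    left[i] = nodes[i].left; right[i] = nodes[i].right;
    value[i] = nodes[i].value;
  }
  return List::create(_["feature"] = feature, _["threshold"] = threshold,
                      _["left"] = left, _["right"] = right,
                      _["value"] = value);
}

// [[Rcpp::export]]
NumericVector predict_tree_cpp(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"], left = tree["left"],
                right = tree["right"];
  NumericVector threshold = tree["threshold"], value = tree["value"];
  int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] >= 0)
      node = (X(i, feature[node]) <= threshold[node]) ? left[node] : right[node];
    out[i] = value[node];
  }
  return out;
}
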