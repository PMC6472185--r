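// Variance-reduction regression trees for gene-regulatory-network inference.
// All randomness (bootstrap rows, candidate features, extra-trees cutpoints)
// goes through R's RNG, so results are reproducible under set.seed().

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

struct Node {
  int feature;      // -1 => leaf
  double threshold;
  int left, right;
  double value;     // leaf mean
};

struct Grower {
  const double *X;  // n x p, column-major
  int n, p;
  const double *y;
  int mtry, min_split, max_depth;
  bool extra;       // extra-trees: one random cutpoint per candidate feature
  std::vector<Node> nodes;
  std::vector<double> importance;  // SSE decrease per feature, / n_train
  int n_train;

  double node_sse(const std::vector<int> &idx, double &mean_out) const {
    double s = 0.0, ss = 0.0;
    for (int i : idx) { s += y[i]; ss += y[i] * y[i]; }
    double n_d = (double)idx.size();
    mean_out = s / n_d;
    double sse = ss - s * s / n_d;
    return sse > 0.0 ? sse : 0.0;
  }

  // best split of `idx` on feature f; returns SSE decrease (<=0 if none)
  double best_split(const std::vector<int> &idx, int f, double parent_sse,
                    double &thr_out) const {
    const double *xf = X + (size_t)f * n;
    size_t m = idx.size();
    std::vector<int> ord(idx);
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return xf[a] < xf[b]; });
    if (xf[ord.front()] == xf[ord.back()]) return -1.0;

    if (extra) {
      double lo = xf[ord.front()], hi = xf[ord.back()];
      double cut = lo + unif_rand() * (hi - lo);
      double sl = 0, ssl = 0, sr = 0, ssr = 0;
      int nl = 0;
      for (int i : idx) {
        if (xf[i] <= cut) { sl += y[i]; ssl += y[i] * y[i]; ++nl; }
        else { sr += y[i]; ssr += y[i] * y[i]; }
      }
      int nr = (int)m - nl;
      if (nl == 0 || nr == 0) return -1.0;
      double sse_l = ssl - sl * sl / nl, sse_r = ssr - sr * sr / nr;
      thr_out = cut;
      return parent_sse - (sse_l > 0 ? sse_l : 0) - (sse_r > 0 ? sse_r : 0);
    }

    // exhaustive scan over distinct boundaries
    double tot = 0;
    for (int i : idx) tot += y[i];
    double run = 0, best = -1.0;
    for (size_t i = 0; i + 1 < m; ++i) {
      run += y[ord[i]];
      if (xf[ord[i]] == xf[ord[i + 1]]) continue;
      double nl = (double)(i + 1), nr = (double)(m - i - 1);
      // decrease = sum_l^2/nl + sum_r^2/nr - tot^2/m  (SSE identity)
      double gain = run * run / nl + (tot - run) * (tot - run) / nr
                    - tot * tot / (double)m;
      if (gain > best) {
        best = gain;
        thr_out = 0.5 * (xf[ord[i]] + xf[ord[i + 1]]);
      }
    }
    return best;
  }

  int build(std::vector<int> &idx, int depth) {
    double mean;
    double sse = node_sse(idx, mean);
    int id = (int)nodes.size();
    nodes.push_back(Node{-1, 0.0, -1, -1, mean});

    if ((int)idx.size() < min_split || depth >= max_depth || sse <= 0.0)
      return id;

    // sample mtry candidate features without replacement
    std::vector<int> feat(p);
    for (int j = 0; j < p; ++j) feat[j] = j;
    int k = std::min(mtry, p);
    int best_f = -1;
    double best_gain = 0.0, best_thr = 0.0;
    for (int j = 0; j < k; ++j) {
      int pick = j + (int)(unif_rand() * (p - j));
      if (pick >= p) pick = p - 1;
      std::swap(feat[j], feat[pick]);
      double thr;
      double gain = best_split(idx, feat[j], sse, thr);
      if (gain > best_gain) { best_gain = gain; best_f = feat[j]; best_thr = thr; }
    }
    if (best_f < 0) return id;

    const double *xf = X + (size_t)best_f * n;
    std::vector<int> lidx, ridx;
    for (int i : idx) (xf[i] <= best_thr ? lidx : ridx).push_back(i);
    if (lidx.empty() || ridx.empty()) return id;

    importance[best_f] += best_gain / (double)n_train;

    nodes[id].feature = best_f;
    nodes[id].threshold = best_thr;
    int l = build(lidx, depth + 1);
    int r = build(ridx, depth + 1);
    nodes[id].left = l;
    nodes[id].right = r;
    return id;
  }

  double predict_row(int row) const {
    int id = 0;
    while (nodes[id].feature >= 0) {
      const double *xf = X + (size_t)nodes[id].feature * n;
      id = (xf[row] <= nodes[id].threshold) ? nodes[id].left : nodes[id].right;
    }
    return nodes[id].value;
  }
};

}  // namespace

// Random-forest / extra-trees ensemble; returns the mean per-feature SSE
// decrease over `ntrees` trees (each tree's contribution scaled by its
// training-set size).
// [[Rcpp::export]]
NumericVector nl_ensemble_importance(NumericMatrix X, NumericVector y,
                                     int ntrees, int mtry, int min_split,
                                     int max_depth, bool extra, bool bootstrap) {
  int n = X.nrow(), p = X.ncol();
  NumericVector total(p);
  for (int t = 0; t < ntrees; ++t) {
    Grower g;
    g.X = REAL(X); g.n = n; g.p = p; g.y = REAL(y);
    g.mtry = mtry; g.min_split = min_split; g.max_depth = max_depth;
    g.extra = extra;
    g.importance.assign(p, 0.0);

    std::vector<int> idx;
    if (bootstrap) {
      idx.resize(n);
      for (int i = 0; i < n; ++i) {
        int r = (int)(unif_rand() * n);
        idx[i] = r < n ? r : n - 1;
      }
    } else {
      idx.resize(n);
      for (int i = 0; i < n; ++i) idx[i] = i;
    }
    g.n_train = n;
    g.build(idx, 0);
    for (int j = 0; j < p; ++j) total[j] += g.importance[j];
  }
  for (int j = 0; j < p; ++j) total[j] /= (double)ntrees;
  return total;
}

// Single tree fit on the rows in train_idx (0-based); returns per-feature
// importance and predictions for every row of X (used by the boosting loop).
// [[Rcpp::export]]
List nl_tree_fit(NumericMatrix X, NumericVector y, IntegerVector train_idx,
                 int mtry, int min_split, int max_depth, bool extra) {
  int n = X.nrow(), p = X.ncol();
  Grower g;
  g.X = REAL(X); g.n = n; g.p = p; g.y = REAL(y);
  g.mtry = mtry; g.min_split = min_split; g.max_depth = max_depth;
  g.extra = extra;
  g.importance.assign(p, 0.0);

  std::vector<int> idx(train_idx.begin(), train_idx.end());
  g.n_train = (int)idx.size();
  g.build(idx, 0);

  NumericVector pred(n), imp(p);
  for (int i = 0; i < n; ++i) pred[i] = g.predict_row(i);
  for (int j = 0; j < p; ++j) imp[j] = g.importance[j];
  return List::create(_["importance"] = imp, _["pred"] = pred);
}
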