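#include <Rcpp.h>
#include <random>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Regression random forest (CART trees, bootstrap resampling, mtry random
// feature subsets) with out-of-bag error and permutation importance.
// Self-contained so that results are reproducible from an integer seed
// independently of R's RNG state.

namespace {

struct Forest {
  // flat node arrays, one vector per field; trees index into them
  std::vector<int> var, left, right;
  std::vector<double> split, pred;
  std::vector<int> root;  // root node index per tree

  int new_node() {
    var.push_back(-1); left.push_back(-1); right.push_back(-1);
    split.push_back(0.0); pred.push_back(0.0);
    return (int)var.size() - 1;
  }

  double predict_one(int tree, const double *x, int p) const {
    int nd = root[tree];
    while (var[nd] >= 0)
      nd = (x[var[nd]] <= split[nd]) ? left[nd] : right[nd];
    (void)p;
    return pred[nd];
  }
};

struct Builder {
  const NumericMatrix &X;
  const NumericVector &y;
  int n, p, mtry, nodesize;
  std::mt19937 &rng;
  Forest &forest;
  std::vector<int> varpool;

  Builder(const NumericMatrix &X_, const NumericVector &y_, int mtry_,
          int nodesize_, std::mt19937 &rng_, Forest &f)
      : X(X_), y(y_), n(X_.nrow()), p(X_.ncol()), mtry(mtry_),
        nodesize(nodesize_), rng(rng_), forest(f), varpool(p) {
    for (int j = 0; j < p; ++j) varpool[j] = j;
  }

  // build node over idx[lo, hi); returns node index
  int build(std::vector<int> &idx, int lo, int hi) {
    int nd = forest.new_node();
    int m = hi - lo;
    double sum = 0.0;
    for (int i = lo; i < hi; ++i) sum += y[idx[i]];
    forest.pred[nd] = sum / m;
    if (m < nodesize || m < 2) return nd;

    // sample mtry candidate variables without replacement
    for (int j = 0; j < mtry; ++j) {
      std::uniform_int_distribution<int> u(j, p - 1);
      std::swap(varpool[j], varpool[u(rng)]);
    }

    double best_gain = 0.0, best_split = 0.0;
    int best_var = -1;
    double sse_parent_num = 0.0;
    for (int i = lo; i < hi; ++i) {
      double d = y[idx[i]] - forest.pred[nd];
      sse_parent_num += d * d;
    }
    if (sse_parent_num <= 1e-12) return nd;

    std::vector<std::pair<double, double>> xy(m);
    for (int jj = 0; jj < mtry; ++jj) {
      int j = varpool[jj];
      for (int i = 0; i < m; ++i)
        xy[i] = {X(idx[lo + i], j), y[idx[lo + i]]};
      std::sort(xy.begin(), xy.end());
      if (xy.front().first == xy.back().first) continue;
      double ls = 0.0, lss = 0.0, rs = 0.0, rss = 0.0;
      for (int i = 0; i < m; ++i) { rs += xy[i].second; rss += xy[i].second * xy[i].second; }
      for (int i = 0; i < m - 1; ++i) {
        double yi = xy[i].second;
        ls += yi; lss += yi * yi; rs -= yi; rss -= yi * yi;
        if (xy[i + 1].first <= xy[i].first) continue;  // not a valid cut
        int nl = i + 1, nr2 = m - nl;
        double sse = (lss - ls * ls / nl) + (rss - rs * rs / nr2);
        double gain = sse_parent_num - sse;
        if (gain > best_gain + 1e-12) {
          best_gain = gain;
          best_var = j;
          best_split = 0.5 * (xy[i].first + xy[i + 1].first);
        }
      }
    }
    if (best_var < 0) return nd;

    int mid = lo;
    for (int i = lo; i < hi; ++i)
      if (X(idx[i], best_var) <= best_split) std::swap(idx[i], idx[mid++]);
    if (mid == lo || mid == hi) return nd;  // degenerate partition guard

    forest.var[nd] = best_var;
    forest.split[nd] = best_split;
    int l = build(idx, lo, mid);
    int r = build(idx, mid, hi);
    forest.left[nd] = l;
    forest.right[nd] = r;
    return nd;
  }
};

}  // namespace

// [[Rcpp::export]]
List rf_regress(NumericMatrix X, NumericVector y, int ntree, int mtry,
                int nodesize, int seed) {
  const int n = X.nrow(), p = X.ncol();
  if (n < 2) stop("need at least 2 observations");
  if (mtry < 1 || mtry > p) stop("mtry out of range");
  std::mt19937 rng((unsigned)seed);
  std::uniform_int_distribution<int> pick(0, n - 1);

  Forest forest;
  std::vector<double> oob_sum(n, 0.0);
  std::vector<int> oob_cnt(n, 0);
  std::vector<double> imp(p, 0.0);
  std::vector<int> imp_cnt(p, 0);
  double err0_sum = 0.0;
  int err0_trees = 0;

  std::vector<int> inbag(n), idx, oob;
  std::vector<double> xrow(p), perm;

  for (int t = 0; t < ntree; ++t) {
    std::fill(inbag.begin(), inbag.end(), 0);
    idx.clear();
    for (int i = 0; i < n; ++i) {
      int k = pick(rng);
      inbag[k]++;
      idx.push_back(k);
    }
    Builder b(X, y, mtry, nodesize, rng, forest);
    forest.root.push_back(-1);
    forest.root.back() = b.build(idx, 0, (int)idx.size());

    oob.clear();
    for (int i = 0; i < n; ++i) if (!inbag[i]) oob.push_back(i);
    if (oob.empty()) continue;

    // OOB predictions for this tree
    double err0 = 0.0;
    std::vector<double> oob_pred(oob.size());
    for (size_t k = 0; k < oob.size(); ++k) {
      int i = oob[k];
      for (int j = 0; j < p; ++j) xrow[j] = X(i, j);
      double ph = forest.predict_one(t, xrow.data(), p);
      oob_pred[k] = ph;
      oob_sum[i] += ph;
      oob_cnt[i]++;
      double d = ph - y[i];
      err0 += d * d;
    }
    err0 /= oob.size();
    err0_sum += err0;
    err0_trees++;

    // permutation importance: shuffle each variable's OOB values
    perm.resize(oob.size());
    for (int j = 0; j < p; ++j) {
      for (size_t k = 0; k < oob.size(); ++k) perm[k] = X(oob[k], j);
      for (size_t k = oob.size(); k > 1; --k) {
        std::uniform_int_distribution<size_t> u(0, k - 1);
        std::swap(perm[k - 1], perm[u(rng)]);
      }
      double errj = 0.0;
      for (size_t k = 0; k < oob.size(); ++k) {
        int i = oob[k];
        for (int jj = 0; jj < p; ++jj) xrow[jj] = X(i, jj);
        xrow[j] = perm[k];
        double d = forest.predict_one(t, xrow.data(), p) - y[i];
        errj += d * d;
      }
      errj /= oob.size();
      imp[j] += errj - err0;
      imp_cnt[j]++;
    }
  }

  double ybar = 0.0;
  for (int i = 0; i < n; ++i) ybar += y[i];
  ybar /= n;
  double vy = 0.0;
  for (int i = 0; i < n; ++i) vy += (y[i] - ybar) * (y[i] - ybar);
  vy /= n;

  double oob_mse = 0.0;
  int n_oob = 0;
  for (int i = 0; i < n; ++i) {
    if (!oob_cnt[i]) continue;
    double d = oob_sum[i] / oob_cnt[i] - y[i];
    oob_mse += d * d;
    n_oob++;
  }
  if (n_oob == 0) stop("no out-of-bag observations; increase ntree");
  oob_mse /= n_oob;

  double mean_err0 = (err0_trees > 0) ? err0_sum / err0_trees : NA_REAL;
  NumericVector importance(p);
  for (int j = 0; j < p; ++j) {
    double mean_inc = imp_cnt[j] ? imp[j] / imp_cnt[j] : NA_REAL;
    importance[j] = (mean_err0 > 0) ? 100.0 * mean_inc / mean_err0 : 0.0;
  }

  return List::create(
      _["oob_mse"] = oob_mse,
      _["var_explained"] = (vy > 0) ? 1.0 - oob_mse / vy : NA_REAL,
      _["importance"] = importance,
      _["mean_tree_oob_mse"] = mean_err0,
      _["n_oob"] = n_oob);
}
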