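#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

// Random forest of binary CART trees with the Gini split criterion and
// mean-decrease-in-impurity variable importance.
//
// Conventions (shared with the pure-R oracle used in the tests):
//  * candidate features at a node are examined in ascending feature order;
//    a split replaces the incumbent only on a strict improvement, so ties
//    go to the lowest feature index and the lowest threshold;
//  * thresholds are midpoints between consecutive distinct sorted values,
//    "left" means x <= threshold;
//  * the importance credited to a split is
//      (n_node / n_tree_samples) * (gini_parent
//        - (n_left/n_node) gini_left - (n_right/n_node) gini_right);
//  * randomness (bootstrap and per-node feature subsampling) comes from R's
//    RNG, so set.seed() on the R side makes fits reproducible.
//
// Trees are returned as node tables (matrix per tree) with columns
// feature (1-based, 0 = leaf), threshold, left, right (1-based node row,
// 0 = none), n0, n1 (training class counts reaching the node).

static inline double gini2(double n0, double n1) {
  double n = n0 + n1;
  if (n <= 0.0) return 0.0;
  double p0 = n0 / n, p1 = n1 / n;
  return 1.0 - p0 * p0 - p1 * p1;
}

struct TreeBuilder {
  const Rcpp::NumericMatrix& X;
  const Rcpp::IntegerVector& y;
  int mtry;
  double n_total;                 // samples in this tree (importance weight)
  std::vector<double> nodes;      // flat rows of 6 doubles
  std::vector<double>& imp;       // per-feature accumulated decrease
  std::vector<int> feat_pool;

  TreeBuilder(const Rcpp::NumericMatrix& X_, const Rcpp::IntegerVector& y_,
              int mtry_, double ntot, std::vector<double>& imp_)
      : X(X_), y(y_), mtry(mtry_), n_total(ntot), imp(imp_) {
    feat_pool.resize(X.ncol());
    for (int i = 0; i < X.ncol(); ++i) feat_pool[i] = i;
  }

  int add_node() {
    nodes.insert(nodes.end(), 6, 0.0);
    return (int)(nodes.size() / 6) - 1;
  }

  int build(std::vector<int>& idx) {
    int me = add_node();
    const int n = (int)idx.size();
    int c1 = 0;
    for (int i = 0; i < n; ++i) c1 += y[idx[i]];
    const int c0 = n - c1;
    nodes[6 * me + 4] = c0;
    nodes[6 * me + 5] = c1;
    double g = gini2(c0, c1);
    if (c0 == 0 || c1 == 0 || n < 2) return me;

    // sample mtry distinct features, then visit in ascending order
    const int G = X.ncol();
    std::vector<int> feats;
    if (mtry >= G) {
      feats = feat_pool;
    } else {
      for (int i = 0; i < mtry; ++i) {
        int j = i + (int)std::floor(unif_rand() * (G - i));
        if (j >= G) j = G - 1;
        std::swap(feat_pool[i], feat_pool[j]);
      }
      feats.assign(feat_pool.begin(), feat_pool.begin() + mtry);
      std::sort(feats.begin(), feats.end());
    }

    double best_dec = 0.0, best_thr = 0.0;
    int best_f = -1;
    std::vector<std::pair<double, int> > vals(n);
    for (size_t fi = 0; fi < feats.size(); ++fi) {
      const int f = feats[fi];
      for (int i = 0; i < n; ++i) vals[i] = std::make_pair(X(idx[i], f), y[idx[i]]);
      std::sort(vals.begin(), vals.end());
      int l0 = 0, l1 = 0;
      for (int i = 1; i < n; ++i) {
        if (vals[i - 1].second) ++l1; else ++l0;
        if (vals[i].first <= vals[i - 1].first) continue;
        double r0 = c0 - l0, r1 = c1 - l1;
        double nl = l0 + l1, nr = r0 + r1;
        double dec = g - (nl / n) * gini2(l0, l1) - (nr / n) * gini2(r0, r1);
        if (dec > best_dec) {
          best_dec = dec;
          best_f = f;
          best_thr = 0.5 * (vals[i - 1].first + vals[i].first);
        }
      }
    }
    if (best_f < 0 || best_dec <= 0.0) return me;

    imp[best_f] += (n / n_total) * best_dec;
    std::vector<int> left, right;
    left.reserve(n); right.reserve(n);
    for (int i = 0; i < n; ++i) {
      if (X(idx[i], best_f) <= best_thr) left.push_back(idx[i]);
      else right.push_back(idx[i]);
    }
    { std::vector<int>().swap(idx); }   // free before recursing
    int li = build(left);
    { std::vector<int>().swap(left); }
    int ri = build(right);
    nodes[6 * me + 0] = best_f + 1;
    nodes[6 * me + 1] = best_thr;
    nodes[6 * me + 2] = li + 1;
    nodes[6 * me + 3] = ri + 1;
    return me;
  }
};

// [[Rcpp::export(name = ".rf_fit")]]
Rcpp::List rf_fit(Rcpp::NumericMatrix X, Rcpp::IntegerVector y,
                  int n_trees, int mtry, bool bootstrap) {
  const int N = X.nrow(), G = X.ncol();
  if (mtry < 1) mtry = 1;
  if (mtry > G) mtry = G;
  std::vector<double> imp(G, 0.0);
  Rcpp::List trees(n_trees);
  for (int t = 0; t < n_trees; ++t) {
    std::vector<int> idx(N);
    if (bootstrap) {
      for (int i = 0; i < N; ++i) {
        int j = (int)std::floor(unif_rand() * N);
        if (j >= N) j = N - 1;
        idx[i] = j;
      }
    } else {
      for (int i = 0; i < N; ++i) idx[i] = i;
    }
    TreeBuilder tb(X, y, mtry, (double)N, imp);
    tb.build(idx);
    const int nn = (int)(tb.nodes.size() / 6);
    Rcpp::NumericMatrix tm(nn, 6);
    for (int r = 0; r < nn; ++r)
      for (int c = 0; c < 6; ++c) tm(r, c) = tb.nodes[6 * r + c];
    trees[t] = tm;
  }
  for (int f = 0; f < G; ++f) imp[f] /= n_trees;
  return Rcpp::List::create(Rcpp::Named("trees") = trees,
                            Rcpp::Named("importance_raw") = Rcpp::wrap(imp));
}

// Mean over trees of the leaf class-1 fraction reached by each sample.
// [[Rcpp::export(name = ".rf_predict_prob")]]
Rcpp::NumericVector rf_predict_prob(Rcpp::List trees, Rcpp::NumericMatrix X) {
  const int N = X.nrow(), T = trees.size();
  Rcpp::NumericVector out(N);
  for (int t = 0; t < T; ++t) {
    Rcpp::NumericMatrix tm = trees[t];
    for (int i = 0; i < N; ++i) {
      int node = 0;
      while ((int)tm(node, 0) != 0) {
        int f = (int)tm(node, 0) - 1;
        node = (X(i, f) <= tm(node, 1)) ? (int)tm(node, 2) - 1
                                        : (int)tm(node, 3) - 1;
      }
      double n0 = tm(node, 4), n1 = tm(node, 5);
      out[i] += (n0 + n1 > 0) ? n1 / (n0 + n1) : 0.5;
    }
  }
  for (int i = 0; i < N; ++i) out[i] /= T;
  return out;
}
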