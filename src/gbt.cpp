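#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <random>
#include <cmath>
using namespace Rcpp;

// Histogram-based gradient-boosted regression trees, squared loss.
// Level-wise growth, quantile binning, deterministic given (data, seed):
// single-threaded with an internal mt19937 for row/column subsampling.
// Trees are returned as flat arrays so the fitted model is a plain R list
// (JSON-serializable for model bundles).

struct Node {
  int feature = -1;      // -1 -> leaf
  double thresh = 0.0;   // go left if x <= thresh
  int left = -1, right = -1;
  double value = 0.0;    // leaf value (already includes learning rate)
};

// [[Rcpp::export(name = ".gbt_train_cpp")]]
List gbt_train_cpp(NumericMatrix X, NumericVector y,
                   int n_trees, int max_depth, double learning_rate,
                   int min_child, double subsample, double colsample,
                   int max_bin, double min_gain, int seed) {
  const int n = X.nrow(), p = X.ncol();
  if (n_trees < 1 || max_depth < 1) stop("invalid tree parameters");
  if (n < 2 * min_child) stop("too few rows for min_child");

  // --- quantile binning ---------------------------------------------------
  std::vector<std::vector<double> > cuts(p);       // upper edges, per feature
  std::vector<std::vector<unsigned char> > bins(p, std::vector<unsigned char>(n));
  {
    std::vector<double> col(n);
    for (int j = 0; j < p; ++j) {
      for (int i = 0; i < n; ++i) col[i] = X(i, j);
      std::vector<double> sorted(col);
      std::sort(sorted.begin(), sorted.end());
      std::vector<double> cj;
      for (int b = 1; b < max_bin; ++b) {
        size_t idx = (size_t)((double)n * b / max_bin);
        if (idx >= (size_t)n) break;
        double lo = sorted[idx - 1], hi = sorted[idx];
        if (hi > lo) cj.push_back((lo + hi) / 2.0);
      }
      cj.erase(std::unique(cj.begin(), cj.end()), cj.end());
      cuts[j] = cj;
      for (int i = 0; i < n; ++i) {
        bins[j][i] = (unsigned char)(std::upper_bound(cj.begin(), cj.end(),
                                                      col[i]) - cj.begin());
      }
    }
  }

  double base = 0.0;
  for (int i = 0; i < n; ++i) base += y[i];
  base /= n;
  std::vector<double> pred(n, base), resid(n);

  std::mt19937 gen((unsigned)seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::vector<double> importance(p, 0.0);

  List trees(n_trees);
  std::vector<int> feat_idx(p);
  for (int j = 0; j < p; ++j) feat_idx[j] = j;

  for (int t = 0; t < n_trees; ++t) {
    for (int i = 0; i < n; ++i) resid[i] = y[i] - pred[i];

    // row subsample
    std::vector<int> rows;
    rows.reserve(n);
    if (subsample < 1.0) {
      for (int i = 0; i < n; ++i) if (unif(gen) < subsample) rows.push_back(i);
      if ((int)rows.size() < 2 * min_child)
        for (int i = 0; i < n; ++i) rows.push_back(i);
    } else {
      for (int i = 0; i < n; ++i) rows.push_back(i);
    }
    // column subsample
    std::vector<int> feats(feat_idx);
    if (colsample < 1.0) {
      std::shuffle(feats.begin(), feats.end(), gen);
      int keep = std::max(1, (int)std::round(colsample * p));
      feats.resize(keep);
      std::sort(feats.begin(), feats.end());
    }

    std::vector<Node> nodes(1);
    std::vector<int> split_bin_of(1, -1);
    std::vector<int> node_of(rows.size(), 0);
    std::vector<int> level = {0};

    for (int depth = 0; depth < max_depth && !level.empty(); ++depth) {
      // node stats
      int n_nodes = (int)nodes.size();
      std::vector<double> node_sum(n_nodes, 0.0);
      std::vector<int> node_cnt(n_nodes, 0);
      for (size_t r = 0; r < rows.size(); ++r) {
        node_sum[node_of[r]] += resid[rows[r]];
        node_cnt[node_of[r]] += 1;
      }
      std::vector<int> next_level;
      std::vector<int> best_feat(n_nodes, -1), best_bin(n_nodes, -1);
      std::vector<double> best_gain(n_nodes, min_gain);

      // histograms: loop features outer, rows inner
      std::vector<double> hsum((size_t)n_nodes * max_bin);
      std::vector<int> hcnt((size_t)n_nodes * max_bin);
      for (int jj : feats) {
        std::fill(hsum.begin(), hsum.end(), 0.0);
        std::fill(hcnt.begin(), hcnt.end(), 0);
        const std::vector<unsigned char> &bj = bins[jj];
        for (size_t r = 0; r < rows.size(); ++r) {
          int nd = node_of[r];
          size_t off = (size_t)nd * max_bin + bj[rows[r]];
          hsum[off] += resid[rows[r]];
          hcnt[off] += 1;
        }
        for (int nd : level) {
          double G = node_sum[nd];
          int N = node_cnt[nd];
          if (N < 2 * min_child) continue;
          double parent = G * G / N;
          double gl = 0.0; int nl = 0;
          int nb = (int)cuts[jj].size();  // splittable bins: 0..nb-1
          size_t off = (size_t)nd * max_bin;
          for (int b = 0; b < nb; ++b) {
            gl += hsum[off + b];
            nl += hcnt[off + b];
            int nr = N - nl;
            if (nl < min_child || nr < min_child) continue;
            double gr = G - gl;
            double gain = gl * gl / nl + gr * gr / nr - parent;
            if (gain > best_gain[nd]) {
              best_gain[nd] = gain; best_feat[nd] = jj; best_bin[nd] = b;
            }
          }
        }
      }

      // apply splits
      std::vector<int> left_id(n_nodes, -1), right_id(n_nodes, -1);
      bool any = false;
      for (int nd : level) {
        if (best_feat[nd] >= 0) {
          Node L, R;
          L.value = R.value = 0.0;
          nodes[nd].feature = best_feat[nd];
          nodes[nd].thresh = cuts[best_feat[nd]][best_bin[nd]];
          split_bin_of[nd] = best_bin[nd];
          left_id[nd] = (int)nodes.size(); nodes.push_back(L);
          split_bin_of.push_back(-1);
          right_id[nd] = (int)nodes.size(); nodes.push_back(R);
          split_bin_of.push_back(-1);
          nodes[nd].left = left_id[nd];
          nodes[nd].right = right_id[nd];
          next_level.push_back(left_id[nd]);
          next_level.push_back(right_id[nd]);
          importance[best_feat[nd]] += best_gain[nd];
          any = true;
        }
      }
      if (!any) break;
      for (size_t r = 0; r < rows.size(); ++r) {
        int nd = node_of[r];
        if (nd < n_nodes && nodes[nd].feature >= 0 && nodes[nd].left >= 0) {
          bool go_left = bins[nodes[nd].feature][rows[r]] <= split_bin_of[nd];
          node_of[r] = go_left ? nodes[nd].left : nodes[nd].right;
        }
      }
      level = next_level;
    }

    // leaf values = shrunken mean residual of in-bag rows
    {
      int n_nodes = (int)nodes.size();
      std::vector<double> lsum(n_nodes, 0.0);
      std::vector<int> lcnt(n_nodes, 0);
      for (size_t r = 0; r < rows.size(); ++r) {
        lsum[node_of[r]] += resid[rows[r]];
        lcnt[node_of[r]] += 1;
      }
      for (int nd = 0; nd < n_nodes; ++nd) {
        if (nodes[nd].feature < 0) {
          nodes[nd].value = lcnt[nd] > 0
              ? learning_rate * lsum[nd] / lcnt[nd] : 0.0;
        }
      }
      // update predictions for all rows via raw-value traversal
      for (int i = 0; i < n; ++i) {
        int nd = 0;
        while (nodes[nd].feature >= 0) {
          nd = (X(i, nodes[nd].feature) <= nodes[nd].thresh)
              ? nodes[nd].left : nodes[nd].right;
        }
        pred[i] += nodes[nd].value;
      }
      int n_out = n_nodes;
      IntegerVector tf(n_out), tl(n_out), tr(n_out);
      NumericVector tt(n_out), tv(n_out);
      for (int nd = 0; nd < n_out; ++nd) {
        tf[nd] = nodes[nd].feature; tt[nd] = nodes[nd].thresh;
        tl[nd] = nodes[nd].left; tr[nd] = nodes[nd].right;
        tv[nd] = nodes[nd].value;
      }
      trees[t] = List::create(_["feature"] = tf, _["thresh"] = tt,
                              _["left"] = tl, _["right"] = tr,
                              _["value"] = tv);
    }
  }

  return List::create(_["base"] = base, _["trees"] = trees,
                      _["importance"] = NumericVector(importance.begin(),
                                                      importance.end()));
}

// [[Rcpp::export(name = ".gbt_predict_cpp")]]
NumericVector gbt_predict_cpp(List trees, double base, NumericMatrix X) {
  const int n = X.nrow();
  NumericVector out(n, base);
  for (int t = 0; t < trees.size(); ++t) {
    List tr = trees[t];
    IntegerVector tf = tr["feature"], tl = tr["left"], trr = tr["right"];
    NumericVector tt = tr["thresh"], tv = tr["value"];
    for (int i = 0; i < n; ++i) {
      int nd = 0;
      while (tf[nd] >= 0) nd = (X(i, tf[nd]) <= tt[nd]) ? tl[nd] : trr[nd];
      out[i] += tv[nd];
    }
  }
  return out;
}
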