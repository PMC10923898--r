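#include <Rcpp.h>
#include <cmath>
#include <random>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Gradient-boosted decision trees for binary classification, in the style of
// XGBoost's exact greedy algorithm: second-order logistic loss, L1/L2 leaf
// regularisation, minimum-gain (gamma) pruning, row/column subsampling, and
// native missing-value handling (a learned default direction per split).
// Kept deliberately small: the training sets this package sees are a few
// hundred to a few thousand rows with <100 features.

namespace {

struct TreeNodes {
  std::vector<int> feat;       // -1 for leaf
  std::vector<double> thr;
  std::vector<int> left, right;
  std::vector<int> defleft;    // 1 = missing goes left
  std::vector<double> value;   // leaf value (already scaled by eta)
  int add_node() {
    feat.push_back(-1); thr.push_back(0.0);
    left.push_back(-1); right.push_back(-1);
    defleft.push_back(1); value.push_back(0.0);
    return (int)feat.size() - 1;
  }
};

inline double soft_threshold(double g, double alpha) {
  if (g > alpha) return g - alpha;
  if (g < -alpha) return g + alpha;
  return 0.0;
}

inline double leaf_weight(double G, double H, double lambda, double alpha) {
  return -soft_threshold(G, alpha) / (H + lambda);
}

inline double score_part(double G, double H, double lambda, double alpha) {
  double t = soft_threshold(G, alpha);
  return t * t / (H + lambda);
}

} // namespace

// [[Rcpp::export(name = ".gbt_train_cpp")]]
List gbt_train_cpp(NumericMatrix X, NumericVector y, NumericVector w,
                   int nrounds, double eta, int max_depth,
                   double min_child_weight, double subsample,
                   double colsample_bytree, double gamma_reg,
                   double lambda_reg, double alpha_reg, int seed) {
  const int n = X.nrow(), p = X.ncol();
  if (n == 0 || p == 0) stop("empty training matrix");
  std::mt19937 rng((unsigned)seed);
  std::vector<double> margin(n, 0.0); // base score 0.5 <=> margin 0

  List trees(nrounds);

  std::vector<double> g(n), h(n);
  std::vector<int> all_rows(n);
  for (int i = 0; i < n; ++i) all_rows[i] = i;
  std::vector<int> all_feats(p);
  for (int j = 0; j < p; ++j) all_feats[j] = j;

  for (int t = 0; t < nrounds; ++t) {
    // gradients at current margin
    for (int i = 0; i < n; ++i) {
      double pr = 1.0 / (1.0 + std::exp(-margin[i]));
      g[i] = w[i] * (pr - y[i]);
      h[i] = w[i] * pr * (1.0 - pr);
    }
    // row subsample (without replacement)
    std::vector<int> rows = all_rows;
    if (subsample < 1.0) {
      std::shuffle(rows.begin(), rows.end(), rng);
      int ns = std::max(1, (int)std::floor(subsample * n));
      rows.resize(ns);
      std::sort(rows.begin(), rows.end());
    }
    // column subsample
    std::vector<int> feats = all_feats;
    if (colsample_bytree < 1.0) {
      std::shuffle(feats.begin(), feats.end(), rng);
      int nf = std::max(1, (int)std::floor(colsample_bytree * p + 0.5));
      feats.resize(nf);
      std::sort(feats.begin(), feats.end());
    }

    // presort sampled rows per sampled feature (missing excluded)
    std::vector<std::vector<int> > order(feats.size());
    for (size_t fi = 0; fi < feats.size(); ++fi) {
      int f = feats[fi];
      std::vector<int>& o = order[fi];
      o.reserve(rows.size());
      for (size_t r = 0; r < rows.size(); ++r)
        if (!NumericMatrix::is_na(X(rows[r], f))) o.push_back(rows[r]);
      std::stable_sort(o.begin(), o.end(), [&](int a, int b) {
        return X(a, f) < X(b, f);
      });
    }

    TreeNodes tree;
    int root = tree.add_node();
    std::vector<int> node_of(n, -1);
    for (size_t r = 0; r < rows.size(); ++r) node_of[rows[r]] = root;
    std::vector<int> active(1, root);

    for (int depth = 0; depth < max_depth && !active.empty(); ++depth) {
      int na = (int)active.size();
      std::vector<int> slot(tree.feat.size(), -1);
      for (int s = 0; s < na; ++s) slot[active[s]] = s;

      std::vector<double> Gtot(na, 0.0), Htot(na, 0.0);
      std::vector<int> cnt(na, 0);
      for (size_t r = 0; r < rows.size(); ++r) {
        int nd = node_of[rows[r]];
        if (nd < 0) continue;
        int s = slot[nd];
        if (s < 0) continue;
        Gtot[s] += g[rows[r]]; Htot[s] += h[rows[r]]; cnt[s]++;
      }

      std::vector<double> best_gain(na, 0.0), best_thr(na, 0.0);
      std::vector<int> best_feat(na, -1), best_defleft(na, 1);

      std::vector<double> GL(na), HL(na), Gnm(na), Hnm(na), lastv(na);
      std::vector<int> seen(na), nleft(na), nnm(na);

      for (size_t fi = 0; fi < feats.size(); ++fi) {
        int f = feats[fi];
        const std::vector<int>& o = order[fi];
        // non-missing totals per node for this feature
        std::fill(Gnm.begin(), Gnm.end(), 0.0);
        std::fill(Hnm.begin(), Hnm.end(), 0.0);
        std::fill(nnm.begin(), nnm.end(), 0);
        for (size_t k = 0; k < o.size(); ++k) {
          int nd = node_of[o[k]];
          if (nd < 0) continue;
          int s = slot[nd];
          if (s < 0) continue;
          Gnm[s] += g[o[k]]; Hnm[s] += h[o[k]]; nnm[s]++;
        }
        std::fill(GL.begin(), GL.end(), 0.0);
        std::fill(HL.begin(), HL.end(), 0.0);
        std::fill(seen.begin(), seen.end(), 0);
        std::fill(nleft.begin(), nleft.end(), 0);

        for (size_t k = 0; k < o.size(); ++k) {
          int r = o[k];
          int nd = node_of[r];
          if (nd < 0) continue;
          int s = slot[nd];
          if (s < 0) continue;
          double v = X(r, f);
          if (seen[s] && v > lastv[s] + 1e-12 && nleft[s] > 0 &&
              nleft[s] < nnm[s]) {
            double thr = 0.5 * (v + lastv[s]);
            double Gmiss = Gtot[s] - Gnm[s], Hmiss = Htot[s] - Hnm[s];
            double base = score_part(Gtot[s], Htot[s], lambda_reg, alpha_reg);
            // missing left
            {
              double gl = GL[s] + Gmiss, hl = HL[s] + Hmiss;
              double gr = Gtot[s] - gl, hr = Htot[s] - hl;
              if (hl >= min_child_weight && hr >= min_child_weight) {
                double gain = 0.5 * (score_part(gl, hl, lambda_reg, alpha_reg) +
                                     score_part(gr, hr, lambda_reg, alpha_reg) -
                                     base) - gamma_reg;
                if (gain > best_gain[s] + 1e-12) {
                  best_gain[s] = gain; best_feat[s] = f;
                  best_thr[s] = thr; best_defleft[s] = 1;
                }
              }
            }
            // missing right
            {
              double gl = GL[s], hl = HL[s];
              double gr = Gtot[s] - gl, hr = Htot[s] - hl;
              if (hl >= min_child_weight && hr >= min_child_weight) {
                double gain = 0.5 * (score_part(gl, hl, lambda_reg, alpha_reg) +
                                     score_part(gr, hr, lambda_reg, alpha_reg) -
                                     base) - gamma_reg;
                if (gain > best_gain[s] + 1e-12) {
                  best_gain[s] = gain; best_feat[s] = f;
                  best_thr[s] = thr; best_defleft[s] = 0;
                }
              }
            }
          }
          GL[s] += g[r]; HL[s] += h[r];
          lastv[s] = v; seen[s] = 1; nleft[s]++;
        }
      }

      // realise splits / leaves, route rows
      std::vector<int> next_active;
      for (int s = 0; s < na; ++s) {
        int nd = active[s];
        if (best_feat[s] < 0 || cnt[s] < 2) {
          tree.feat[nd] = -1;
          tree.value[nd] = eta * leaf_weight(Gtot[s], Htot[s], lambda_reg,
                                            alpha_reg);
        } else {
          int L = tree.add_node();
          int R = tree.add_node();
          slot.resize(tree.feat.size(), -1);
          tree.feat[nd] = best_feat[s];
          tree.thr[nd] = best_thr[s];
          tree.defleft[nd] = best_defleft[s];
          tree.left[nd] = L;
          tree.right[nd] = R;
          next_active.push_back(L);
          next_active.push_back(R);
        }
      }
      for (size_t r = 0; r < rows.size(); ++r) {
        int i = rows[r];
        int nd = node_of[i];
        if (nd < 0 || tree.feat[nd] < 0) continue;
        double v = X(i, tree.feat[nd]);
        bool go_left = NumericMatrix::is_na(v) ? (tree.defleft[nd] == 1)
                                               : (v < tree.thr[nd]);
        node_of[i] = go_left ? tree.left[nd] : tree.right[nd];
      }
      active = next_active;
    }
    // remaining active nodes at max depth become leaves
    if (!active.empty()) {
      std::vector<double> G2(active.size(), 0.0), H2(active.size(), 0.0);
      std::vector<int> slot(tree.feat.size(), -1);
      for (size_t s = 0; s < active.size(); ++s) slot[active[s]] = (int)s;
      for (size_t r = 0; r < rows.size(); ++r) {
        int nd = node_of[rows[r]];
        if (nd < 0) continue;
        int s = slot[nd];
        if (s < 0) continue;
        G2[s] += g[rows[r]]; H2[s] += h[rows[r]];
      }
      for (size_t s = 0; s < active.size(); ++s) {
        int nd = active[s];
        tree.feat[nd] = -1;
        tree.value[nd] = eta * leaf_weight(G2[s], H2[s], lambda_reg, alpha_reg);
      }
    }

    // update margins for every row (also out-of-sample ones)
    for (int i = 0; i < n; ++i) {
      int nd = 0;
      while (tree.feat[nd] >= 0) {
        double v = X(i, tree.feat[nd]);
        bool go_left = NumericMatrix::is_na(v) ? (tree.defleft[nd] == 1)
                                               : (v < tree.thr[nd]);
        nd = go_left ? tree.left[nd] : tree.right[nd];
      }
      margin[i] += tree.value[nd];
    }

    trees[t] = List::create(
        _["feat"] = IntegerVector(tree.feat.begin(), tree.feat.end()),
        _["thr"] = NumericVector(tree.thr.begin(), tree.thr.end()),
        _["left"] = IntegerVector(tree.left.begin(), tree.left.end()),
        _["right"] = IntegerVector(tree.right.begin(), tree.right.end()),
        _["defleft"] = IntegerVector(tree.defleft.begin(), tree.defleft.end()),
        _["value"] = NumericVector(tree.value.begin(), tree.value.end()));
  }
  return trees;
}

// [[Rcpp::export(name = ".gbt_predict_cpp")]]
NumericVector gbt_predict_cpp(List trees, NumericMatrix X) {
  const int n = X.nrow();
  NumericVector out(n);
  for (int t = 0; t < trees.size(); ++t) {
    List tr = trees[t];
    IntegerVector feat = tr["feat"];
    NumericVector thr = tr["thr"];
    IntegerVector left = tr["left"];
    IntegerVector right = tr["right"];
    IntegerVector defleft = tr["defleft"];
    NumericVector value = tr["value"];
    for (int i = 0; i < n; ++i) {
      int nd = 0;
      while (feat[nd] >= 0) {
        double v = X(i, feat[nd]);
        bool go_left = NumericMatrix::is_na(v) ? (defleft[nd] == 1)
                                               : (v < thr[nd]);
        nd = go_left ? left[nd] : right[nd];
      }
      out[i] += value[nd];
    }
  }
  for (int i = 0; i < n; ++i) out[i] = 1.0 / (1.0 + std::exp(-out[i]));
  return out;
}
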