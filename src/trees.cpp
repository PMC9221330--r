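// Native tree learners backing the four base classifiers, plus the
// accepted-reference ectopic scan (hot loop over raw samples).
//
// One builder covers both classification (Gini, exhaustive or
// random-threshold splits, feature subsampling) and weighted regression
// (variance reduction), so CART, extremely randomized trees and both
// boosting flavours share the same kernel.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
LogicalVector cpp_detect_ectopic(NumericVector x, double threshold) {
  int n = x.size();
  LogicalVector mask(n);
  double ref = 0.0;
  bool have_ref = false;
  for (int i = 0; i < n; ++i) {
    double v = x[i];
    if (!R_finite(v)) { mask[i] = true; continue; }      // missing sample
    if (!have_ref) { mask[i] = false; ref = v; have_ref = true; continue; }
    if (ref == 0.0) { mask[i] = true; continue; }        // undefined ratio
    double rel = std::fabs(v - ref) / std::fabs(ref);
    if (rel > threshold) { mask[i] = true; }
    else { mask[i] = false; ref = v; }
  }
  return mask;
}

namespace {

struct Node {
  int feature;      // -1 for leaf
  double threshold;
  int left, right;
  double value;               // regression leaf value
  std::vector<double> dist;   // classification leaf distribution
};

struct Params {
  int max_depth, min_split, mtry;
  bool random_split;
  bool regression;
  int n_classes;
};

struct Builder {
  const NumericMatrix& X;
  const IntegerVector& ycls;
  const NumericVector& yreg;
  const NumericVector& w;
  Params par;
  std::vector<int> idx;
  std::vector<Node> nodes;
  std::vector<double> importance;

  Builder(const NumericMatrix& X_, const IntegerVector& yc,
          const NumericVector& yr, const NumericVector& w_, Params p)
      : X(X_), ycls(yc), yreg(yr), w(w_), par(p),
        importance(X_.ncol(), 0.0) {
    idx.resize(X.nrow());
    for (int i = 0; i < X.nrow(); ++i) idx[i] = i;
  }

  // impurity * total weight for samples [lo, hi)
  double node_impurity(int lo, int hi, std::vector<double>& counts,
                       double& wsum) const {
    wsum = 0.0;
    if (par.regression) {
      double s = 0, q = 0;
      for (int t = lo; t < hi; ++t) {
        int i = idx[t];
        wsum += w[i]; s += w[i] * yreg[i]; q += w[i] * yreg[i] * yreg[i];
      }
      if (wsum <= 0) return 0.0;
      return q - s * s / wsum;  // weighted SSE
    }
    std::fill(counts.begin(), counts.end(), 0.0);
    for (int t = lo; t < hi; ++t) {
      int i = idx[t];
      counts[ycls[i]] += w[i];
      wsum += w[i];
    }
    double g = wsum;
    for (int k = 0; k < par.n_classes; ++k) g -= counts[k] * counts[k] / wsum;
    return g;  // wsum * gini
  }

  bool find_best_split(int lo, int hi, double parent_imp, int& best_f,
                       double& best_thr, double& best_gain) {
    int p = X.ncol();
    int mtry = std::min(par.mtry, p);
    // partial Fisher-Yates over feature ids using R's RNG
    std::vector<int> feats(p);
    for (int j = 0; j < p; ++j) feats[j] = j;
    for (int j = 0; j < mtry; ++j) {
      int pick = j + (int)std::floor(unif_rand() * (p - j));
      if (pick >= p) pick = p - 1;
      std::swap(feats[j], feats[pick]);
    }
    best_gain = 1e-12;
    bool found = false;
    int n = hi - lo, K = par.n_classes;
    std::vector<std::pair<double,int> > vals(n);
    std::vector<double> cl(K), cr(K);
    for (int jj = 0; jj < mtry; ++jj) {
      int f = feats[jj];
      double vmin = R_PosInf, vmax = R_NegInf;
      for (int t = lo; t < hi; ++t) {
        double v = X(idx[t], f);
        if (v < vmin) vmin = v;
        if (v > vmax) vmax = v;
      }
      if (!(vmax > vmin)) continue;
      if (par.random_split) {
        double thr = vmin + unif_rand() * (vmax - vmin);
        double wl = 0, wr = 0, il, ir;
        if (par.regression) {
          double sl = 0, ql = 0, sr = 0, qr = 0;
          for (int t = lo; t < hi; ++t) {
            int i = idx[t];
            if (X(i, f) <= thr) { wl += w[i]; sl += w[i]*yreg[i]; ql += w[i]*yreg[i]*yreg[i]; }
            else { wr += w[i]; sr += w[i]*yreg[i]; qr += w[i]*yreg[i]*yreg[i]; }
          }
          if (wl <= 0 || wr <= 0) continue;
          il = ql - sl * sl / wl; ir = qr - sr * sr / wr;
        } else {
          std::fill(cl.begin(), cl.end(), 0.0);
          std::fill(cr.begin(), cr.end(), 0.0);
          for (int t = lo; t < hi; ++t) {
            int i = idx[t];
            if (X(i, f) <= thr) { cl[ycls[i]] += w[i]; wl += w[i]; }
            else { cr[ycls[i]] += w[i]; wr += w[i]; }
          }
          if (wl <= 0 || wr <= 0) continue;
          il = wl; ir = wr;
          for (int k = 0; k < K; ++k) { il -= cl[k]*cl[k]/wl; ir -= cr[k]*cr[k]/wr; }
        }
        double gain = parent_imp - il - ir;
        if (gain > best_gain) { best_gain = gain; best_f = f; best_thr = thr; found = true; }
      } else {
        for (int t = lo; t < hi; ++t) vals[t - lo] = std::make_pair(X(idx[t], f), idx[t]);
        std::sort(vals.begin(), vals.begin() + n);
        if (par.regression) {
          double wl = 0, sl = 0, ql = 0;
          double wt = 0, st = 0, qt = 0;
          for (int t = 0; t < n; ++t) {
            int i = vals[t].second;
            wt += w[i]; st += w[i]*yreg[i]; qt += w[i]*yreg[i]*yreg[i];
          }
          for (int t = 0; t < n - 1; ++t) {
            int i = vals[t].second;
            wl += w[i]; sl += w[i]*yreg[i]; ql += w[i]*yreg[i]*yreg[i];
            if (vals[t + 1].first <= vals[t].first) continue;
            double wr2 = wt - wl, sr2 = st - sl, qr2 = qt - ql;
            if (wl <= 0 || wr2 <= 0) continue;
            double gain = parent_imp - (ql - sl*sl/wl) - (qr2 - sr2*sr2/wr2);
            if (gain > best_gain) {
              best_gain = gain; best_f = f;
              best_thr = 0.5 * (vals[t].first + vals[t + 1].first);
              found = true;
            }
          }
        } else {
          std::fill(cl.begin(), cl.end(), 0.0);
          std::vector<double> ct(K, 0.0);
          double wt = 0;
          for (int t = 0; t < n; ++t) { int i = vals[t].second; ct[ycls[i]] += w[i]; wt += w[i]; }
          double wl = 0;
          for (int t = 0; t < n - 1; ++t) {
            int i = vals[t].second;
            cl[ycls[i]] += w[i]; wl += w[i];
            if (vals[t + 1].first <= vals[t].first) continue;
            double wr2 = wt - wl;
            if (wl <= 0 || wr2 <= 0) continue;
            double il = wl, ir = wr2;
            for (int k = 0; k < K; ++k) {
              il -= cl[k]*cl[k]/wl;
              double crk = ct[k] - cl[k];
              ir -= crk*crk/wr2;
            }
            double gain = parent_imp - il - ir;
            if (gain > best_gain) {
              best_gain = gain; best_f = f;
              best_thr = 0.5 * (vals[t].first + vals[t + 1].first);
              found = true;
            }
          }
        }
      }
    }
    return found;
  }

  int build(int lo, int hi, int depth) {
    int me = (int)nodes.size();
    nodes.push_back(Node());
    std::vector<double> counts(par.regression ? 0 : par.n_classes);
    double wsum;
    double imp = node_impurity(lo, hi, counts, wsum);
    bool stop = (depth >= par.max_depth) || (hi - lo < par.min_split) ||
                (imp <= 1e-12) || (wsum <= 0);
    int best_f = -1; double best_thr = 0, best_gain = 0;
    if (!stop) stop = !find_best_split(lo, hi, imp, best_f, best_thr, best_gain);
    if (stop) {
      Node& nd = nodes[me];
      nd.feature = -1; nd.left = nd.right = -1; nd.threshold = 0;
      if (par.regression) {
        double s = 0;
        for (int t = lo; t < hi; ++t) { int i = idx[t]; s += w[i] * yreg[i]; }
        nd.value = wsum > 0 ? s / wsum : 0.0;
      } else {
        nd.dist.assign(par.n_classes, 0.0);
        for (int k = 0; k < par.n_classes; ++k)
          nd.dist[k] = wsum > 0 ? counts[k] / wsum : 1.0 / par.n_classes;
      }
      return me;
    }
    importance[best_f] += best_gain;
    // partition idx[lo,hi) in place
    int a = lo, b = hi - 1;
    while (a <= b) {
      if (X(idx[a], best_f) <= best_thr) ++a;
      else { std::swap(idx[a], idx[b]); --b; }
    }
    int mid = a;
    if (mid == lo || mid == hi) {  // numerically degenerate; make leaf
      nodes[me].feature = -1; nodes[me].left = nodes[me].right = -1;
      if (par.regression) {
        double s = 0;
        for (int t = lo; t < hi; ++t) { int i = idx[t]; s += w[i] * yreg[i]; }
        nodes[me].value = wsum > 0 ? s / wsum : 0.0;
      } else {
        nodes[me].dist.assign(par.n_classes, 0.0);
        for (int k = 0; k < par.n_classes; ++k)
          nodes[me].dist[k] = wsum > 0 ? counts[k] / wsum : 1.0 / par.n_classes;
      }
      return me;
    }
    int l = build(lo, mid, depth + 1);
    int r = build(mid, hi, depth + 1);
    Node& nd = nodes[me];
    nd.feature = best_f; nd.threshold = best_thr; nd.left = l; nd.right = r;
    return me;
  }
};

List pack_tree(const Builder& B, bool regression, int n_classes) {
  int m = (int)B.nodes.size();
  IntegerVector feature(m), left(m), right(m);
  NumericVector threshold(m), value(m);
  NumericMatrix dist(regression ? 1 : m, regression ? 1 : n_classes);
  for (int i = 0; i < m; ++i) {
    feature[i] = B.nodes[i].feature;
    threshold[i] = B.nodes[i].threshold;
    left[i] = B.nodes[i].left;
    right[i] = B.nodes[i].right;
    if (regression) value[i] = B.nodes[i].value;
    else if (B.nodes[i].feature < 0)
      for (int k = 0; k < n_classes; ++k) dist(i, k) = B.nodes[i].dist[k];
  }
  return List::create(_["feature"] = feature, _["threshold"] = threshold,
                      _["left"] = left, _["right"] = right,
                      _["value"] = value, _["dist"] = dist,
                      _["importance"] = NumericVector(B.importance.begin(),
                                                      B.importance.end()));
}

int descend(const IntegerVector& feature, const NumericVector& threshold,
            const IntegerVector& left, const IntegerVector& right,
            const NumericMatrix& X, int row) {
  int node = 0;
  while (feature[node] >= 0) {
    node = (X(row, feature[node]) <= threshold[node]) ? left[node] : right[node];
  }
  return node;
}

}  // namespace

// [[Rcpp::export]]
List cpp_grow_cls_tree(NumericMatrix X, IntegerVector y, int n_classes,
                       NumericVector w, int max_depth, int min_split,
                       int mtry, bool random_split) {
  Params p; p.max_depth = max_depth; p.min_split = min_split; p.mtry = mtry;
  p.random_split = random_split; p.regression = false; p.n_classes = n_classes;
  NumericVector dummy(0);
  Builder B(X, y, dummy, w, p);
  GetRNGstate();
  B.build(0, X.nrow(), 0);
  PutRNGstate();
  return pack_tree(B, false, n_classes);
}

// [[Rcpp::export]]
List cpp_grow_reg_tree(NumericMatrix X, NumericVector y, NumericVector w,
                       int max_depth, int min_split, int mtry,
                       bool random_split) {
  Params p; p.max_depth = max_depth; p.min_split = min_split; p.mtry = mtry;
  p.random_split = random_split; p.regression = true; p.n_classes = 0;
  IntegerVector dummy(0);
  Builder B(X, dummy, y, w, p);
  GetRNGstate();
  B.build(0, X.nrow(), 0);
  PutRNGstate();
  return pack_tree(B, true, 0);
}

// [[Rcpp::export]]
NumericMatrix cpp_predict_cls_tree(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"], left = tree["left"],
                right = tree["right"];
  NumericVector threshold = tree["threshold"];
  NumericMatrix dist = tree["dist"];
  int n = X.nrow(), K = dist.ncol();
  NumericMatrix out(n, K);
  for (int i = 0; i < n; ++i) {
    int leaf = descend(feature, threshold, left, right, X, i);
    for (int k = 0; k < K; ++k) out(i, k) = dist(leaf, k);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_predict_reg_tree(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"], left = tree["left"],
                right = tree["right"];
  NumericVector threshold = tree["threshold"], value = tree["value"];
  int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = value[descend(feature, threshold, left, right, X, i)];
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_leaf_ids(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"], left = tree["left"],
                right = tree["right"];
  NumericVector threshold = tree["threshold"];
  int n = X.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = descend(feature, threshold, left, right, X, i);
  return out;
}
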