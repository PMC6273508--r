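#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Minimal random-forest classifier with out-of-bag (OOB) permutation
// accuracy importance. CART trees, Gini impurity, mtry features per node,
// bootstrap sampling. Self-contained xorshift RNG so results depend only on
// the seed argument, not on R's RNG state.

namespace {

struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s << 13; s ^= s >> 7; s ^= s << 17;
    return s;
  }
  // uniform integer in [0, n)
  int below(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

struct Node {
  int feat;       // -1 for leaf
  double thr;
  int left, right;
  int pred;
};

struct Tree {
  std::vector<Node> nodes;
  std::vector<int> used_feats;
};

int majority(const std::vector<int> &cnt, Rng &rng) {
  int best = 0;
  for (size_t c = 1; c < cnt.size(); ++c) if (cnt[c] > cnt[best]) best = (int)c;
  (void)rng;
  return best;
}

double gini_from_counts(const std::vector<int> &cnt, int n) {
  if (n == 0) return 0.0;
  double g = 1.0;
  for (int c : cnt) { double f = (double)c / n; g -= f * f; }
  return g;
}

void build_node(const NumericMatrix &X, const IntegerVector &y, int ncls,
                std::vector<int> &idx, int lo, int hi, int depth,
                int mtry, int min_node, int max_depth,
                Tree &tree, Rng &rng, std::vector<char> &feat_seen) {
  const int n = hi - lo;
  std::vector<int> cnt(ncls, 0);
  for (int t = lo; t < hi; ++t) cnt[y[idx[t]]]++;
  int me = (int)tree.nodes.size();
  tree.nodes.push_back(Node{-1, 0.0, -1, -1, majority(cnt, rng)});

  bool pure = false;
  for (int c = 0; c < ncls; ++c) if (cnt[c] == n) pure = true;
  if (pure || n < min_node || depth >= max_depth) return;

  const int p = X.ncol();
  // sample mtry distinct features
  std::vector<int> feats(p);
  for (int f = 0; f < p; ++f) feats[f] = f;
  for (int k = 0; k < mtry && k < p; ++k) std::swap(feats[k], feats[k + rng.below(p - k)]);

  const double parent_imp = gini_from_counts(cnt, n);
  double best_gain = 1e-12;
  int best_f = -1; double best_thr = 0.0;

  std::vector<std::pair<double,int> > vals(n);
  for (int k = 0; k < mtry && k < p; ++k) {
    const int f = feats[k];
    for (int t = 0; t < n; ++t) vals[t] = std::make_pair(X(idx[lo + t], f), y[idx[lo + t]]);
    std::sort(vals.begin(), vals.end());
    if (vals.front().first == vals.back().first) continue;
    std::vector<int> lc(ncls, 0), rc(cnt);
    for (int t = 0; t < n - 1; ++t) {
      lc[vals[t].second]++; rc[vals[t].second]--;
      if (vals[t].first == vals[t + 1].first) continue;
      const int nl = t + 1, nr = n - nl;
      const double gain = parent_imp -
        ((double)nl / n) * gini_from_counts(lc, nl) -
        ((double)nr / n) * gini_from_counts(rc, nr);
      if (gain > best_gain) {
        best_gain = gain; best_f = f;
        best_thr = 0.5 * (vals[t].first + vals[t + 1].first);
      }
    }
  }
  if (best_f < 0) return;

  // partition idx[lo..hi) in place
  int mid = lo;
  for (int t = lo; t < hi; ++t)
    if (X(idx[t], best_f) <= best_thr) std::swap(idx[t], idx[mid++]);
  if (mid == lo || mid == hi) return;

  tree.nodes[me].feat = best_f;
  tree.nodes[me].thr = best_thr;
  if (!feat_seen[best_f]) { feat_seen[best_f] = 1; tree.used_feats.push_back(best_f); }
  tree.nodes[me].left = (int)tree.nodes.size();
  build_node(X, y, ncls, idx, lo, mid, depth + 1, mtry, min_node, max_depth, tree, rng, feat_seen);
  tree.nodes[me].right = (int)tree.nodes.size();
  build_node(X, y, ncls, idx, mid, hi, depth + 1, mtry, min_node, max_depth, tree, rng, feat_seen);
}

int predict_one(const Tree &tree, const NumericMatrix &X, int row,
                int perm_feat, double perm_val) {
  int cur = 0;
  for (;;) {
    const Node &nd = tree.nodes[cur];
    if (nd.feat < 0) return nd.pred;
    const double v = (nd.feat == perm_feat) ? perm_val : X(row, nd.feat);
    cur = (v <= nd.thr) ? nd.left : nd.right;
  }
}

} // namespace

// [[Rcpp::export]]
List cpp_rf_importance(NumericMatrix X, IntegerVector y, int ncls,
                       int ntree, int mtry, int min_node, int max_depth,
                       double seed) {
  const int n = X.nrow(), p = X.ncol();
  Rng rng(static_cast<uint64_t>(seed) * 2654435761ULL + 1ULL);

  std::vector<double> importance(p, 0.0);
  NumericMatrix oob_votes(n, ncls);
  std::vector<int> inbag(n), oob;
  std::vector<int> idx;
  std::vector<char> feat_seen(p, 0);

  for (int tr = 0; tr < ntree; ++tr) {
    std::fill(inbag.begin(), inbag.end(), 0);
    idx.clear();
    for (int t = 0; t < n; ++t) { int s = rng.below(n); inbag[s]++; idx.push_back(s); }
    oob.clear();
    for (int t = 0; t < n; ++t) if (!inbag[t]) oob.push_back(t);

    Tree tree;
    std::fill(feat_seen.begin(), feat_seen.end(), 0);
    build_node(X, y, ncls, idx, 0, (int)idx.size(), 0, mtry, min_node, max_depth,
               tree, rng, feat_seen);

    if (oob.empty()) continue;
    const int no = (int)oob.size();

    std::vector<int> base_pred(no);
    int base_correct = 0;
    for (int t = 0; t < no; ++t) {
      base_pred[t] = predict_one(tree, X, oob[t], -1, 0.0);
      oob_votes(oob[t], base_pred[t]) += 1.0;
      if (base_pred[t] == y[oob[t]]) ++base_correct;
    }
    const double base_acc = (double)base_correct / no;

    // permutation importance restricted to features actually split on
    std::vector<int> perm(no);
    for (int uf : tree.used_feats) {
      for (int t = 0; t < no; ++t) perm[t] = t;
      for (int t = no - 1; t > 0; --t) std::swap(perm[t], perm[rng.below(t + 1)]);
      int correct = 0;
      for (int t = 0; t < no; ++t) {
        const double pv = X(oob[perm[t]], uf);
        if (predict_one(tree, X, oob[t], uf, pv) == y[oob[t]]) ++correct;
      }
      importance[uf] += base_acc - (double)correct / no;
    }
  }

  for (int f = 0; f < p; ++f) importance[f] /= ntree;
  return List::create(_["importance"] = NumericVector(importance.begin(), importance.end()),
                      _["oob_votes"] = oob_votes);
}
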