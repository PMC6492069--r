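// Random-forest classifier: bagged CART trees, Gini impurity splits,
// per-node feature subsampling, leaf class-distribution averaging for
// probability output, and impurity-decrease feature importances.
//
// Self-contained RNG (splitmix64/xorshift) so that fits are bit-for-bit
// reproducible from an integer seed, independent of R's RNG state.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

namespace {

struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) {
    // splitmix64 scramble so small seeds diverge immediately
    s = seed + 0x9E3779B97F4A7C15ULL;
    next();
    next();
  }
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform integer in [0, n)
  int unif_int(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

inline double gini(const std::vector<double>& counts, double n) {
  if (n <= 0) return 0.0;
  double s = 0.0;
  for (double c : counts) s += c * c;
  return 1.0 - s / (n * n);
}

struct Tree {
  std::vector<int> feature;      // -1 for leaf
  std::vector<double> threshold; // go left if x <= threshold
  std::vector<int> left, right;
  std::vector<std::vector<double>> leaf_prob;

  int new_node() {
    feature.push_back(-1);
    threshold.push_back(0.0);
    left.push_back(-1);
    right.push_back(-1);
    leaf_prob.push_back(std::vector<double>());
    return static_cast<int>(feature.size()) - 1;
  }
};

struct BuildItem {
  int node;
  int begin, end; // range in the sample-index workspace
  int depth;
};

} // namespace

// [[Rcpp::export(name = ".rf_fit_cpp")]]
List rf_fit_cpp(NumericMatrix X, IntegerVector y, int nclass, int ntree,
                int mtry, int min_node, int max_depth, int seed) {
  const int n = X.nrow(), p = X.ncol();
  if (n < 1) stop("empty training set");
  if (mtry < 1 || mtry > p) stop("mtry out of range");
  NumericVector importance(p);

  List trees(ntree);
  std::vector<int> feat_pool(p);

  for (int t = 0; t < ntree; ++t) {
    Rng rng(static_cast<uint64_t>(seed) * 2654435761ULL + 0x9E3779B9ULL * (t + 1));

    // bootstrap sample (with replacement)
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = rng.unif_int(n);

    Tree tree;
    std::vector<BuildItem> stack;
    int root = tree.new_node();
    stack.push_back({root, 0, n, 0});

    std::vector<double> cnt(nclass), lcnt(nclass), rcnt(nclass), best_l(nclass);

    while (!stack.empty()) {
      BuildItem it = stack.back();
      stack.pop_back();
      const int m = it.end - it.begin;

      std::fill(cnt.begin(), cnt.end(), 0.0);
      for (int i = it.begin; i < it.end; ++i) cnt[y[idx[i]]] += 1.0;
      const double imp = gini(cnt, m);

      bool make_leaf = (m < std::max(2, 2 * min_node)) || imp <= 0.0 ||
                       (max_depth > 0 && it.depth >= max_depth);

      int best_f = -1;
      double best_thr = 0.0, best_dec = 1e-12;
      int best_pos = -1;

      if (!make_leaf) {
        // sample mtry features without replacement (partial Fisher-Yates)
        for (int j = 0; j < p; ++j) feat_pool[j] = j;
        for (int j = 0; j < mtry; ++j) {
          int k = j + rng.unif_int(p - j);
          std::swap(feat_pool[j], feat_pool[k]);
        }
        std::vector<int> ord(idx.begin() + it.begin, idx.begin() + it.end);
        for (int j = 0; j < mtry; ++j) {
          const int f = feat_pool[j];
          std::sort(ord.begin(), ord.end(), [&](int a, int b) {
            return X(a, f) < X(b, f);
          });
          std::fill(lcnt.begin(), lcnt.end(), 0.0);
          double nl = 0.0;
          for (int i = 0; i < m - 1; ++i) {
            lcnt[y[ord[i]]] += 1.0;
            nl += 1.0;
            const double xv = X(ord[i], f), xn = X(ord[i + 1], f);
            if (xv == xn) continue;
            if (nl < min_node || (m - nl) < min_node) continue;
            for (int c = 0; c < nclass; ++c) rcnt[c] = cnt[c] - lcnt[c];
            const double dec =
                imp - (nl * gini(lcnt, nl) + (m - nl) * gini(rcnt, m - nl)) / m;
            if (dec > best_dec) {
              best_dec = dec;
              best_f = f;
              best_thr = xv + (xn - xv) / 2.0;
              if (best_thr <= xv) best_thr = xv; // guard against underflow
              best_pos = static_cast<int>(nl);
              std::copy(lcnt.begin(), lcnt.end(), best_l.begin());
            }
          }
        }
      }

      if (best_f < 0) {
        std::vector<double> prob(nclass);
        for (int c = 0; c < nclass; ++c) prob[c] = cnt[c] / m;
        tree.leaf_prob[it.node] = prob;
        continue;
      }

      importance[best_f] += best_dec * m / n;

      // partition the index range around the threshold
      std::vector<int>::iterator mid = std::partition(
          idx.begin() + it.begin, idx.begin() + it.end,
          [&](int a) { return X(a, best_f) <= best_thr; });
      int split_at = static_cast<int>(mid - idx.begin());
      if (split_at == it.begin || split_at == it.end) {
        // numeric pathology: fall back to a leaf
        std::vector<double> prob(nclass);
        for (int c = 0; c < nclass; ++c) prob[c] = cnt[c] / m;
        tree.feature[it.node] = -1;
        tree.leaf_prob[it.node] = prob;
        continue;
      }
      (void)best_pos;

      tree.feature[it.node] = best_f;
      tree.threshold[it.node] = best_thr;
      int lnode = tree.new_node();
      int rnode = tree.new_node();
      tree.left[it.node] = lnode;
      tree.right[it.node] = rnode;
      stack.push_back({rnode, split_at, it.end, it.depth + 1});
      stack.push_back({lnode, it.begin, split_at, it.depth + 1});
    }

    const int nn = static_cast<int>(tree.feature.size());
    NumericMatrix probs(nn, nclass);
    for (int i = 0; i < nn; ++i)
      if (tree.feature[i] < 0)
        for (int c = 0; c < nclass; ++c) probs(i, c) = tree.leaf_prob[i][c];
    trees[t] = List::create(
        _["feature"] = IntegerVector(tree.feature.begin(), tree.feature.end()),
        _["threshold"] = NumericVector(tree.threshold.begin(), tree.threshold.end()),
        _["left"] = IntegerVector(tree.left.begin(), tree.left.end()),
        _["right"] = IntegerVector(tree.right.begin(), tree.right.end()),
        _["prob"] = probs);
  }

  return List::create(_["trees"] = trees, _["importance"] = importance,
                      _["nclass"] = nclass, _["ntree"] = ntree);
}

// [[Rcpp::export(name = ".rf_predict_cpp")]]
NumericMatrix rf_predict_cpp(List forest, NumericMatrix X) {
  const int n = X.nrow();
  const int nclass = as<int>(forest["nclass"]);
  List trees = forest["trees"];
  const int ntree = trees.size();
  NumericMatrix out(n, nclass);

  for (int t = 0; t < ntree; ++t) {
    List tr = trees[t];
    IntegerVector feature = tr["feature"];
    NumericVector threshold = tr["threshold"];
    IntegerVector left = tr["left"], right = tr["right"];
    NumericMatrix prob = tr["prob"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feature[node] >= 0)
        node = (X(i, feature[node]) <= threshold[node]) ? left[node] : right[node];
      for (int c = 0; c < nclass; ++c) out(i, c) += prob(node, c);
    }
  }
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < nclass; ++c) out(i, c) /= ntree;
  return out;
}
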