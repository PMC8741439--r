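// Bagged classification trees with out-of-bag (OOB) error and permutation
// importance, and per-leaf positive-class fractions for response scoring.
//
// The ensemble is deliberately self-contained and deterministic: bootstrap
// draws and permutations come from an internal splitmix64 stream, one
// substream per tree, so results are bit-identical for a given (data, seed)
// on any platform, independent of R's RNG state.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>

using namespace Rcpp;

namespace {

struct SplitMix64 {
  uint64_t s;
  explicit SplitMix64(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform integer in [0, n)
  int bounded(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

inline uint64_t substream(uint64_t seed, uint64_t k) {
  return seed * 0x9E3779B97F4A7C15ULL + (k + 1) * 0xBF58476D1CE4E5B9ULL;
}

// tree nodes in parallel arrays; feature == -1 marks a leaf
struct Tree {
  std::vector<int> feature;
  std::vector<double> threshold;
  std::vector<int> left, right;
  std::vector<double> frac;   // in-bag positive-class fraction at the node
  std::vector<int> n_node;    // in-bag observation count
};

double gini(int n_pos, int n) {
  if (n == 0) return 0.0;
  double p = static_cast<double>(n_pos) / n;
  return 2.0 * p * (1.0 - p);
}

// recursively grow a node over in-bag observation indices (with multiplicity)
int grow(Tree& tr, const NumericMatrix& X, const IntegerVector& y,
         std::vector<int>& obs, int lo, int hi, int min_node, int depth,
         SplitMix64& rng) {
  int n = hi - lo;
  int n_pos = 0;
  for (int i = lo; i < hi; ++i) n_pos += y[obs[i]];

  int node = static_cast<int>(tr.feature.size());
  tr.feature.push_back(-1);
  tr.threshold.push_back(0.0);
  tr.left.push_back(-1);
  tr.right.push_back(-1);
  tr.frac.push_back(static_cast<double>(n_pos) / n);
  tr.n_node.push_back(n);

  double parent = gini(n_pos, n);
  if (n_pos == 0 || n_pos == n || n < 2 * min_node || n < 2 || depth > 64 || parent <= 0.0)
    return node;

  // best split over all features; exact-gain ties (common when many genes
  // separate the in-bag classes perfectly) are broken uniformly at random
  // by reservoir sampling from the tree's own deterministic stream
  int best_f = -1;
  double best_thr = 0.0, best_gain = 1e-12;
  int n_ties = 0;
  const double eps = 1e-12;
  int p = X.ncol();
  std::vector<int> idx(obs.begin() + lo, obs.begin() + hi);

  for (int j = 0; j < p; ++j) {
    std::sort(idx.begin(), idx.end(), [&](int a, int b) {
      double xa = X(a, j), xb = X(b, j);
      if (xa != xb) return xa < xb;
      return a < b;                       // deterministic order
    });
    int lp = 0;                           // positives in left partition
    for (int i = 0; i < n - 1; ++i) {
      lp += y[idx[i]];
      double xv = X(idx[i], j), xn = X(idx[i + 1], j);
      if (xv == xn) continue;             // can only split between distinct values
      int nl = i + 1, nr = n - nl;
      if (nl < min_node || nr < min_node) continue;
      double g = parent
        - (static_cast<double>(nl) / n) * gini(lp, nl)
        - (static_cast<double>(nr) / n) * gini(n_pos - lp, nr);
      if (g > best_gain + eps) {
        best_gain = g;
        best_f = j;
        best_thr = xv + 0.5 * (xn - xv);  // midpoint
        n_ties = 1;
      } else if (best_f >= 0 && g >= best_gain - eps) {
        ++n_ties;
        if (rng.bounded(n_ties) == 0) {
          best_f = j;
          best_thr = xv + 0.5 * (xn - xv);
        }
      }
    }
  }
  if (best_f < 0) return node;

  // partition observations (stable) around the split
  std::vector<int> lobs, robs;
  for (int i = lo; i < hi; ++i) {
    if (X(obs[i], best_f) <= best_thr) lobs.push_back(obs[i]);
    else robs.push_back(obs[i]);
  }
  std::copy(lobs.begin(), lobs.end(), obs.begin() + lo);
  std::copy(robs.begin(), robs.end(), obs.begin() + lo + lobs.size());

  tr.feature[node] = best_f;
  tr.threshold[node] = best_thr;
  int mid = lo + static_cast<int>(lobs.size());
  tr.left[node] = grow(tr, X, y, obs, lo, mid, min_node, depth + 1, rng);
  tr.right[node] = grow(tr, X, y, obs, mid, hi, min_node, depth + 1, rng);
  return node;
}

double leaf_frac(const Tree& tr, const NumericMatrix& X, int row) {
  int node = 0;
  while (tr.feature[node] >= 0)
    node = (X(row, tr.feature[node]) <= tr.threshold[node]) ? tr.left[node] : tr.right[node];
  return tr.frac[node];
}

double leaf_frac_perm(const Tree& tr, const NumericMatrix& X, int row,
                      int perm_feature, double perm_value) {
  int node = 0;
  while (tr.feature[node] >= 0) {
    double v = (tr.feature[node] == perm_feature) ? perm_value : X(row, tr.feature[node]);
    node = (v <= tr.threshold[node]) ? tr.left[node] : tr.right[node];
  }
  return tr.frac[node];
}

Tree tree_from_list(const List& tl) {
  Tree tr;
  tr.feature = as<std::vector<int>>(tl["feature"]);
  tr.threshold = as<std::vector<double>>(tl["threshold"]);
  tr.left = as<std::vector<int>>(tl["left"]);
  tr.right = as<std::vector<int>>(tl["right"]);
  tr.frac = as<std::vector<double>>(tl["frac"]);
  return tr;
}

// leaf fraction > 0.5 votes positive; exact ties vote negative
inline int vote(double frac) { return frac > 0.5 ? 1 : 0; }

} // namespace

// [[Rcpp::export]]
List cpp_forest_fit(NumericMatrix X, IntegerVector y, int n_trees,
                    double seed, int min_node) {
  int n = X.nrow();
  List trees(n_trees);
  IntegerMatrix inbag(n, n_trees);
  uint64_t base = static_cast<uint64_t>(seed);

  for (int t = 0; t < n_trees; ++t) {
    SplitMix64 rng(substream(base, static_cast<uint64_t>(t)));
    std::vector<int> obs(n);
    for (int i = 0; i < n; ++i) {
      int d = rng.bounded(n);
      obs[i] = d;
      inbag(d, t) += 1;
    }
    Tree tr;
    grow(tr, X, y, obs, 0, n, min_node, 0, rng);
    trees[t] = List::create(_["feature"] = wrap(tr.feature),
                            _["threshold"] = wrap(tr.threshold),
                            _["left"] = wrap(tr.left),
                            _["right"] = wrap(tr.right),
                            _["frac"] = wrap(tr.frac),
                            _["n_node"] = wrap(tr.n_node));
  }
  return List::create(_["trees"] = trees, _["inbag"] = inbag);
}

// mean over all trees of the positive-class fraction in the leaf each
// observation falls into: the response score
// [[Rcpp::export]]
NumericVector cpp_forest_score(List trees, NumericMatrix X) {
  int n = X.nrow(), T = trees.size();
  NumericVector out(n);
  for (int t = 0; t < T; ++t) {
    Tree tr = tree_from_list(trees[t]);
    for (int i = 0; i < n; ++i) out[i] += leaf_frac(tr, X, i);
  }
  for (int i = 0; i < n; ++i) out[i] /= T;
  return out;
}

// OOB score (mean leaf fraction over trees not containing the observation)
// and OOB misclassification error over observations with >= 1 OOB tree
// [[Rcpp::export]]
List cpp_forest_oob(List trees, IntegerMatrix inbag, NumericMatrix X, IntegerVector y) {
  int n = X.nrow(), T = trees.size();
  NumericVector score(n);
  IntegerVector cnt(n);
  for (int t = 0; t < T; ++t) {
    Tree tr = tree_from_list(trees[t]);
    for (int i = 0; i < n; ++i) {
      if (inbag(i, t) == 0) {
        score[i] += leaf_frac(tr, X, i);
        cnt[i] += 1;
      }
    }
  }
  int n_used = 0, n_err = 0;
  for (int i = 0; i < n; ++i) {
    if (cnt[i] > 0) {
      score[i] /= cnt[i];
      ++n_used;
      if (vote(score[i]) != y[i]) ++n_err;
    } else {
      score[i] = NA_REAL;
    }
  }
  double err = n_used > 0 ? static_cast<double>(n_err) / n_used : NA_REAL;
  return List::create(_["oob_error"] = err, _["oob_score"] = score,
                      _["n_oob_trees"] = cnt);
}

// OOB permutation importance: mean over trees of the decrease in OOB accuracy
// after permuting one feature's values among that tree's OOB observations
// [[Rcpp::export]]
NumericVector cpp_forest_importance(List trees, IntegerMatrix inbag,
                                    NumericMatrix X, IntegerVector y, double seed) {
  int n = X.nrow(), p = X.ncol(), T = trees.size();
  NumericVector imp(p);
  int t_used = 0;
  uint64_t base = static_cast<uint64_t>(seed) ^ 0xA5A5A5A5A5A5A5A5ULL;

  for (int t = 0; t < T; ++t) {
    std::vector<int> oob;
    for (int i = 0; i < n; ++i) if (inbag(i, t) == 0) oob.push_back(i);
    int m = static_cast<int>(oob.size());
    if (m == 0) continue;
    ++t_used;
    Tree tr = tree_from_list(trees[t]);

    int correct = 0;
    for (int k = 0; k < m; ++k)
      if (vote(leaf_frac(tr, X, oob[k])) == y[oob[k]]) ++correct;
    double acc = static_cast<double>(correct) / m;

    // which features does this tree actually use? others get importance 0
    std::vector<bool> used(p, false);
    for (size_t nd = 0; nd < tr.feature.size(); ++nd)
      if (tr.feature[nd] >= 0) used[tr.feature[nd]] = true;

    SplitMix64 rng(substream(base, static_cast<uint64_t>(t)));
    for (int j = 0; j < p; ++j) {
      if (!used[j]) continue;   // permuting an unused feature changes nothing
      // Fisher-Yates permutation of feature j's OOB values
      std::vector<double> v(m);
      for (int k = 0; k < m; ++k) v[k] = X(oob[k], j);
      for (int k = m - 1; k > 0; --k) std::swap(v[k], v[rng.bounded(k + 1)]);
      int corr_p = 0;
      for (int k = 0; k < m; ++k)
        if (vote(leaf_frac_perm(tr, X, oob[k], j, v[k])) == y[oob[k]]) ++corr_p;
      imp[j] += acc - static_cast<double>(corr_p) / m;
    }
  }
  if (t_used > 0) for (int j = 0; j < p; ++j) imp[j] /= t_used;
  return imp;
}
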