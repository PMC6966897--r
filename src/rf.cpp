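// Balanced-bootstrap random forest classifier (binary), with out-of-bag
// error, Gini-decrease and permutation (mean-decrease-accuracy) importances.
// Implemented from scratch: no tree learner ships with the target library
// set. Trees are fully grown CART stumps-to-depth with Gini splitting and
// sqrt(p) feature subsampling, each fitted on an equal-count bootstrap of the
// two classes so class imbalance does not dominate the vote.
#include <Rcpp.h>
#include <random>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct Node {
  int feat = -1;       // -1 => leaf
  double thr = 0.0;
  int left = -1, right = -1;
  double prob = 0.0;   // class-1 fraction at leaf
};

struct Tree {
  std::vector<Node> nodes;
};

struct Builder {
  const NumericMatrix &X;
  const IntegerVector &y;
  int mtry, min_node;
  std::mt19937_64 &eng;
  std::uniform_real_distribution<double> unif{0.0, 1.0};
  std::vector<double> &gini_imp;
  Tree tree;

  Builder(const NumericMatrix &X, const IntegerVector &y, int mtry,
          int min_node, std::mt19937_64 &eng, std::vector<double> &gi)
      : X(X), y(y), mtry(mtry), min_node(min_node), eng(eng), gini_imp(gi) {}

  int build(std::vector<int> &idx) {
    int id = (int)tree.nodes.size();
    tree.nodes.push_back(Node());
    int n = (int)idx.size(), n1 = 0;
    for (int i : idx) n1 += y[i];
    double p1 = (double)n1 / n;
    tree.nodes[id].prob = p1;
    if (n < 2 * min_node || n1 == 0 || n1 == n) return id;

    int p = X.ncol();
    std::vector<int> feats(p);
    for (int f = 0; f < p; ++f) feats[f] = f;
    for (int f = 0; f < mtry; ++f) {
      int r = f + (int)(unif(eng) * (p - f));
      if (r >= p) r = p - 1;
      std::swap(feats[f], feats[r]);
    }

    double imp_parent = 1.0 - p1 * p1 - (1.0 - p1) * (1.0 - p1);
    double best_gain = 1e-12, best_thr = 0.0;
    int best_feat = -1;
    std::vector<std::pair<double, int>> vals(n);
    for (int fi = 0; fi < mtry; ++fi) {
      int f = feats[fi];
      for (int i = 0; i < n; ++i) vals[i] = {X(idx[i], f), y[idx[i]]};
      std::sort(vals.begin(), vals.end());
      int l1 = 0;
      for (int i = 0; i < n - 1; ++i) {
        l1 += vals[i].second;
        if (vals[i + 1].first <= vals[i].first) continue; // tied values
        int nl = i + 1, nr = n - nl, r1 = n1 - l1;
        double pl = (double)l1 / nl, pr = (double)r1 / nr;
        double il = 1.0 - pl * pl - (1.0 - pl) * (1.0 - pl);
        double ir = 1.0 - pr * pr - (1.0 - pr) * (1.0 - pr);
        double gain = imp_parent - (nl * il + nr * ir) / n;
        if (gain > best_gain) {
          best_gain = gain;
          best_feat = f;
          best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
        }
      }
    }
    if (best_feat < 0) return id;

    std::vector<int> li, ri;
    for (int i : idx)
      (X(i, best_feat) <= best_thr ? li : ri).push_back(i);
    if (li.empty() || ri.empty()) return id;
    gini_imp[best_feat] += best_gain * n;
    tree.nodes[id].feat = best_feat;
    tree.nodes[id].thr = best_thr;
    int l = build(li);
    int r = build(ri);
    tree.nodes[id].left = l;
    tree.nodes[id].right = r;
    return id;
  }
};

inline double tree_prob(const Tree &t, const NumericMatrix &X, int row,
                        int perm_feat, const std::vector<int> &perm_src) {
  int id = 0;
  for (;;) {
    const Node &nd = t.nodes[id];
    if (nd.feat < 0) return nd.prob;
    double v = (nd.feat == perm_feat) ? X(perm_src[row], nd.feat)
                                      : X(row, nd.feat);
    id = (v <= nd.thr) ? nd.left : nd.right;
  }
}

} // namespace

// [[Rcpp::export]]
List rf_train_cpp(NumericMatrix X, IntegerVector y, int n_trees, int mtry,
                  int min_node, double seed) {
  const int n = X.nrow(), p = X.ncol();
  std::mt19937_64 eng((unsigned long)seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  std::vector<int> idx0, idx1;
  for (int i = 0; i < n; ++i) (y[i] ? idx1 : idx0).push_back(i);
  const int per_class = (int)std::min(idx0.size(), idx1.size());

  std::vector<double> gini_imp(p, 0.0), mda(p, 0.0);
  std::vector<double> oob_prob(n, 0.0);
  std::vector<int> oob_n(n, 0);
  std::vector<Tree> forest;
  forest.reserve(n_trees);

  std::vector<int> inbag(n), bag, oob, perm_id(n);
  for (int t = 0; t < n_trees; ++t) {
    std::fill(inbag.begin(), inbag.end(), 0);
    bag.clear();
    for (int k = 0; k < per_class; ++k) {
      int a = idx0[(int)(unif(eng) * idx0.size())];
      int b = idx1[(int)(unif(eng) * idx1.size())];
      bag.push_back(a);
      bag.push_back(b);
      inbag[a] = 1;
      inbag[b] = 1;
    }
    Builder bd(X, y, mtry, min_node, eng, gini_imp);
    bd.build(bag);
    forest.push_back(std::move(bd.tree));
    const Tree &tr = forest.back();

    oob.clear();
    for (int i = 0; i < n; ++i)
      if (!inbag[i]) oob.push_back(i);
    if (oob.empty()) continue;
    for (int i = 0; i < n; ++i) perm_id[i] = i;
    int correct = 0;
    for (int i : oob) {
      double pr = tree_prob(tr, X, i, -1, perm_id);
      oob_prob[i] += pr;
      ++oob_n[i];
      if ((pr > 0.5 ? 1 : 0) == y[i]) ++correct;
    }
    double acc = (double)correct / oob.size();
    // permutation importance on the OOB set
    std::vector<int> shuffled(oob);
    for (int f = 0; f < p; ++f) {
      for (int k = (int)shuffled.size() - 1; k > 0; --k) {
        int r = (int)(unif(eng) * (k + 1));
        std::swap(shuffled[k], shuffled[r]);
      }
      for (size_t k = 0; k < oob.size(); ++k) perm_id[oob[k]] = shuffled[k];
      int cp = 0;
      for (int i : oob) {
        double pr = tree_prob(tr, X, i, f, perm_id);
        if ((pr > 0.5 ? 1 : 0) == y[i]) ++cp;
      }
      mda[f] += acc - (double)cp / oob.size();
      for (int i : oob) perm_id[i] = i;
    }
  }

  // class-balanced (macro-averaged) OOB error: mean of the two per-class
  // misclassification rates, so imbalance cannot collapse it to the
  // majority-class rate
  int covered = 0;
  int cls_n[2] = {0, 0}, cls_mis[2] = {0, 0};
  for (int i = 0; i < n; ++i) {
    if (oob_n[i] == 0) continue;
    ++covered;
    int pred = (oob_prob[i] / oob_n[i] > 0.5) ? 1 : 0;
    ++cls_n[y[i]];
    if (pred != y[i]) ++cls_mis[y[i]];
  }
  double oob_err = NA_REAL;
  if (cls_n[0] > 0 && cls_n[1] > 0) {
    oob_err = 0.5 * ((double)cls_mis[0] / cls_n[0] +
                     (double)cls_mis[1] / cls_n[1]);
  } else if (covered > 0) {
    oob_err = (double)(cls_mis[0] + cls_mis[1]) / covered;
  }

  List trees(n_trees);
  for (int t = 0; t < n_trees; ++t) {
    const Tree &tr = forest[t];
    NumericMatrix m(tr.nodes.size(), 5);
    for (size_t k = 0; k < tr.nodes.size(); ++k) {
      m(k, 0) = tr.nodes[k].feat;
      m(k, 1) = tr.nodes[k].thr;
      m(k, 2) = tr.nodes[k].left;
      m(k, 3) = tr.nodes[k].right;
      m(k, 4) = tr.nodes[k].prob;
    }
    trees[t] = m;
  }
  for (int f = 0; f < p; ++f) mda[f] /= n_trees;

  return List::create(
      _["trees"] = trees,
      _["oob_error"] = oob_err,
      _["oob_covered"] = covered,
      _["importance_gini"] = NumericVector(gini_imp.begin(), gini_imp.end()),
      _["importance_mda"] = NumericVector(mda.begin(), mda.end()));
}

// Average class-1 leaf fraction across trees.
// [[Rcpp::export]]
NumericVector rf_predict_cpp(List trees, NumericMatrix X) {
  int n = X.nrow();
  NumericVector out(n);
  std::vector<int> id(n);
  for (int i = 0; i < n; ++i) id[i] = i;
  for (int t = 0; t < trees.size(); ++t) {
    NumericMatrix m = trees[t];
    for (int i = 0; i < n; ++i) {
      int nd = 0;
      for (;;) {
        int feat = (int)m(nd, 0);
        if (feat < 0) {
          out[i] += m(nd, 4);
          break;
        }
        nd = (X(i, feat) <= m(nd, 1)) ? (int)m(nd, 2) : (int)m(nd, 3);
      }
    }
  }
  for (int i = 0; i < n; ++i) out[i] /= trees.size();
  return out;
}
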