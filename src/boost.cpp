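// Gradient-boosted decision trees for binary classification.
//
// Second-order (Newton) boosting with exact greedy splits, logistic loss.
// The trainer keeps a running margin for an optional validation set so the
// per-iteration validation loss curve comes out of a single pass; nested
// cross-validation uses that curve to pick the optimal round count.
//
// Trees are returned as flat matrices (one row per node) so fitted models
// serialize to plain R objects.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Node {
  int feature;    // -1 for leaf
  double thresh;  // go left if x <= thresh
  int left, right;
  double value;   // leaf weight (unscaled by eta)
};

inline double sigmoid(double m) { return 1.0 / (1.0 + std::exp(-m)); }

// Build one tree on rows with gradients g, hessians h.
// Exact greedy, level-wise, using per-feature presorted row orders.
void build_tree(const NumericMatrix& X,
                const std::vector<std::vector<int>>& order,
                const std::vector<double>& g,
                const std::vector<double>& h,
                int max_depth, double lambda, double min_child_weight,
                std::vector<Node>& nodes, std::vector<int>& leaf_of_row,
                std::vector<double>& feat_gain) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<int> node_of(n, 0);  // current node of each row (-1: inactive)
  nodes.clear();
  {
    double G = 0, H = 0;
    for (int i = 0; i < n; ++i) { G += g[i]; H += h[i]; }
    Node root; root.feature = -1; root.thresh = 0;
    root.left = root.right = -1; root.value = -G / (H + lambda);
    nodes.push_back(root);
  }
  std::vector<int> active(1, 0);
  std::vector<double> Gn(1), Hn(1);
  Gn[0] = 0; Hn[0] = 0;
  for (int i = 0; i < n; ++i) { Gn[0] += g[i]; Hn[0] += h[i]; }

  for (int depth = 0; depth < max_depth && !active.empty(); ++depth) {
    const int na = (int)active.size();
    // index of node within active set, -1 if not active
    std::vector<int> slot(nodes.size(), -1);
    for (int a = 0; a < na; ++a) slot[active[a]] = a;

    std::vector<double> best_gain(na, 0.0), best_thresh(na, 0.0);
    std::vector<int> best_feat(na, -1);

    std::vector<double> GL(na), HL(na), lastval(na);
    std::vector<char> seen(na);
    for (int f = 0; f < p; ++f) {
      std::fill(GL.begin(), GL.end(), 0.0);
      std::fill(HL.begin(), HL.end(), 0.0);
      std::fill(seen.begin(), seen.end(), 0);
      const std::vector<int>& ord = order[f];
      for (int k = 0; k < n; ++k) {
        const int i = ord[k];
        const int nd = node_of[i];
        if (nd < 0 || slot[nd] < 0) continue;
        const int a = slot[nd];
        const double x = X(i, f);
        if (seen[a] && x > lastval[a]) {
          // candidate split between lastval and x
          const double GR = Gn[a] - GL[a];
          const double HR = Hn[a] - HL[a];
          if (HL[a] >= min_child_weight && HR >= min_child_weight) {
            const double gain =
              GL[a] * GL[a] / (HL[a] + lambda) + GR * GR / (HR + lambda) -
              Gn[a] * Gn[a] / (Hn[a] + lambda);
            if (gain > best_gain[a] + 1e-12) {
              best_gain[a] = gain;
              best_feat[a] = f;
              best_thresh[a] = 0.5 * (lastval[a] + x);
            }
          }
        }
        GL[a] += g[i]; HL[a] += h[i];
        lastval[a] = x; seen[a] = 1;
      }
    }

    // split the improvable nodes, reassign rows
    std::vector<int> next_active;
    std::vector<double> nGn, nHn;
    std::vector<char> splits(na, 0);
    for (int a = 0; a < na; ++a) {
      if (best_feat[a] < 0 || best_gain[a] <= 0) continue;
      splits[a] = 1;
      const int id = active[a];
      nodes[id].feature = best_feat[a];
      nodes[id].thresh = best_thresh[a];
      feat_gain[best_feat[a]] += 0.5 * best_gain[a];
      Node l, r;
      l.feature = r.feature = -1; l.thresh = r.thresh = 0;
      l.left = l.right = r.left = r.right = -1;
      l.value = r.value = 0;
      nodes[id].left = (int)nodes.size(); nodes.push_back(l);
      nodes[id].right = (int)nodes.size(); nodes.push_back(r);
      next_active.push_back(nodes[id].left);
      next_active.push_back(nodes[id].right);
      nGn.push_back(0); nHn.push_back(0);
      nGn.push_back(0); nHn.push_back(0);
    }
    slot.resize(nodes.size(), -1);
    std::vector<int> nslot(nodes.size(), -1);
    for (size_t a = 0; a < next_active.size(); ++a) nslot[next_active[a]] = (int)a;
    for (int i = 0; i < n; ++i) {
      const int nd = node_of[i];
      if (nd < 0 || slot[nd] < 0 || !splits[slot[nd]]) continue;
      const Node& nod = nodes[nd];
      const int child = (X(i, nod.feature) <= nod.thresh) ? nod.left : nod.right;
      node_of[i] = child;
      const int a = nslot[child];
      nGn[a] += g[i]; nHn[a] += h[i];
    }
    for (size_t a = 0; a < next_active.size(); ++a) {
      const int id = next_active[a];
      nodes[id].value = -nGn[a] / (nHn[a] + lambda);
    }
    active = next_active;
    Gn = nGn; Hn = nHn;
  }
  leaf_of_row = node_of;
  // rows in nodes that stopped splitting keep that node as their leaf
}

inline double tree_value(const std::vector<Node>& nodes, const NumericMatrix& X, int i) {
  int id = 0;
  while (nodes[id].feature >= 0)
    id = (X(i, nodes[id].feature) <= nodes[id].thresh) ? nodes[id].left : nodes[id].right;
  return nodes[id].value;
}

NumericMatrix pack_tree(const std::vector<Node>& nodes) {
  NumericMatrix m((int)nodes.size(), 5);
  for (size_t k = 0; k < nodes.size(); ++k) {
    m(k, 0) = nodes[k].feature;  // -1 => leaf (0-based feature otherwise)
    m(k, 1) = nodes[k].thresh;
    m(k, 2) = nodes[k].left;
    m(k, 3) = nodes[k].right;
    m(k, 4) = nodes[k].value;
  }
  colnames(m) = CharacterVector::create("feature", "thresh", "left", "right", "value");
  return m;
}

}  // namespace

// [[Rcpp::export(name = ".boost_train_cpp")]]
List boost_train_cpp(NumericMatrix X, NumericVector y,
                     int nrounds, double eta, int max_depth,
                     double lambda, double min_child_weight,
                     Nullable<NumericMatrix> Xval_ = R_NilValue,
                     Nullable<NumericVector> yval_ = R_NilValue) {
  const int n = X.nrow(), p = X.ncol();
  if (n < 2) stop("need at least 2 training rows");

  bool has_val = Xval_.isNotNull();
  NumericMatrix Xval;
  NumericVector yval;
  int nv = 0;
  if (has_val) {
    Xval = NumericMatrix(Xval_);
    yval = NumericVector(yval_);
    nv = Xval.nrow();
  }

  // presort row orders per feature
  std::vector<std::vector<int>> order(p);
  for (int f = 0; f < p; ++f) {
    order[f].resize(n);
    for (int i = 0; i < n; ++i) order[f][i] = i;
    const int ff = f;
    std::stable_sort(order[f].begin(), order[f].end(),
                     [&X, ff](int a, int b) { return X(a, ff) < X(b, ff); });
  }

  std::vector<double> margin(n, 0.0), vmargin(nv, 0.0);  // base_score 0.5 => margin 0
  std::vector<double> g(n), h(n), feat_gain(p, 0.0);
  NumericVector val_loss(has_val ? nrounds : 0);
  List trees(nrounds);

  std::vector<Node> nodes;
  std::vector<int> leaf_of_row;
  for (int r = 0; r < nrounds; ++r) {
    for (int i = 0; i < n; ++i) {
      const double pr = sigmoid(margin[i]);
      g[i] = pr - y[i];
      h[i] = std::max(pr * (1.0 - pr), 1e-16);
    }
    build_tree(X, order, g, h, max_depth, lambda, min_child_weight,
               nodes, leaf_of_row, feat_gain);
    for (int i = 0; i < n; ++i) margin[i] += eta * nodes[leaf_of_row[i]].value;
    trees[r] = pack_tree(nodes);
    if (has_val) {
      double ll = 0;
      for (int i = 0; i < nv; ++i) {
        vmargin[i] += eta * tree_value(nodes, Xval, i);
        const double pr = std::min(std::max(sigmoid(vmargin[i]), 1e-15), 1.0 - 1e-15);
        ll -= yval[i] * std::log(pr) + (1.0 - yval[i]) * std::log(1.0 - pr);
      }
      val_loss[r] = ll / nv;
    }
  }

  NumericVector fg(feat_gain.begin(), feat_gain.end());
  return List::create(_["trees"] = trees, _["feature_gain"] = fg,
                      _["val_loss"] = val_loss, _["eta"] = eta,
                      _["nrounds"] = nrounds);
}

// [[Rcpp::export(name = ".boost_predict_cpp")]]
NumericVector boost_predict_cpp(List trees, NumericMatrix X, double eta,
                                int nrounds) {
  const int n = X.nrow();
  NumericVector margin(n, 0.0);
  const int use = std::min<int>(nrounds, trees.size());
  for (int r = 0; r < use; ++r) {
    NumericMatrix t = trees[r];
    for (int i = 0; i < n; ++i) {
      int id = 0;
      while (t(id, 0) >= 0)
        id = (X(i, (int)t(id, 0)) <= t(id, 1)) ? (int)t(id, 2) : (int)t(id, 3);
      margin[i] += eta * t(id, 4);
    }
  }
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = sigmoid(margin[i]);
  return out;
}
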