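#include <Rcpp.h>
using namespace Rcpp;

// Random forest of CART trees with the information-gain (entropy) split
// criterion.  Bootstrap rows, mtry features per node, grown until pure or
// below min_node.  All randomness comes from R's RNG so forests are
// reproducible under set.seed().

namespace {

struct Tree {
  std::vector<int> feat;                 // -1 for leaf
  std::vector<double> thr;
  std::vector<int> left, right;
  std::vector< std::vector<double> > prob;  // leaf class distribution
};

double entropy(const std::vector<int>& cnt, int total) {
  if (total == 0) return 0.0;
  double h = 0.0;
  for (size_t c = 0; c < cnt.size(); ++c) {
    if (cnt[c] > 0) {
      double p = (double)cnt[c] / total;
      h -= p * std::log(p);
    }
  }
  return h;
}

int rand_int(int n) {  // uniform on 0..n-1 via R RNG
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

class Builder {
public:
  const NumericMatrix& X;
  const IntegerVector& y;
  int g, mtry, min_node;
  Tree tree;

  Builder(const NumericMatrix& X_, const IntegerVector& y_, int g_, int mtry_,
          int min_node_) : X(X_), y(y_), g(g_), mtry(mtry_), min_node(min_node_) {}

  int make_leaf(const std::vector<int>& idx) {
    std::vector<int> cnt(g, 0);
    for (size_t k = 0; k < idx.size(); ++k) cnt[y[idx[k]]]++;
    std::vector<double> p(g, 0.0);
    for (int c = 0; c < g; ++c) p[c] = (double)cnt[c] / idx.size();
    tree.feat.push_back(-1); tree.thr.push_back(0.0);
    tree.left.push_back(-1); tree.right.push_back(-1);
    tree.prob.push_back(p);
    return (int)tree.feat.size() - 1;
  }

  int build(std::vector<int>& idx) {
    int nI = (int)idx.size();
    std::vector<int> cnt(g, 0);
    for (int k = 0; k < nI; ++k) cnt[y[idx[k]]]++;
    int nz = 0; for (int c = 0; c < g; ++c) if (cnt[c] > 0) ++nz;
    if (nz <= 1 || nI <= min_node) return make_leaf(idx);

    double parentH = entropy(cnt, nI);
    int p = X.ncol();
    // sample mtry distinct features
    std::vector<int> feats(p);
    for (int j = 0; j < p; ++j) feats[j] = j;
    int mt = std::min(mtry, p);
    for (int j = 0; j < mt; ++j) std::swap(feats[j], feats[j + rand_int(p - j)]);

    double bestGain = 1e-12; int bestF = -1; double bestThr = 0.0;
    std::vector< std::pair<double,int> > vals(nI);
    for (int fj = 0; fj < mt; ++fj) {
      int f = feats[fj];
      for (int k = 0; k < nI; ++k) vals[k] = std::make_pair(X(idx[k], f), y[idx[k]]);
      std::sort(vals.begin(), vals.end());
      std::vector<int> lc(g, 0), rc(cnt);
      for (int k = 0; k < nI - 1; ++k) {
        lc[vals[k].second]++; rc[vals[k].second]--;
        if (vals[k].first == vals[k + 1].first) continue;
        int nl = k + 1, nr = nI - nl;
        double childH = (nl * entropy(lc, nl) + nr * entropy(rc, nr)) / nI;
        double gain = parentH - childH;
        if (gain > bestGain) {
          bestGain = gain; bestF = f;
          bestThr = 0.5 * (vals[k].first + vals[k + 1].first);
        }
      }
    }
    if (bestF < 0) return make_leaf(idx);

    std::vector<int> li, ri;
    for (int k = 0; k < nI; ++k) {
      if (X(idx[k], bestF) <= bestThr) li.push_back(idx[k]);
      else ri.push_back(idx[k]);
    }
    if (li.empty() || ri.empty()) return make_leaf(idx);

    int node = (int)tree.feat.size();
    tree.feat.push_back(bestF); tree.thr.push_back(bestThr);
    tree.left.push_back(-1); tree.right.push_back(-1);
    tree.prob.push_back(std::vector<double>());
    int l = build(li); int r = build(ri);
    tree.feat[node] = bestF; tree.left[node] = l; tree.right[node] = r;
    return node;
  }
};

}  // namespace

// [[Rcpp::export]]
List rf_fit_cpp(NumericMatrix X, IntegerVector y, int g, int ntree, int mtry,
                int min_node) {
  RNGScope scope;
  int n = X.nrow();
  List forest(ntree);
  for (int b = 0; b < ntree; ++b) {
    std::vector<int> idx(n);
    for (int k = 0; k < n; ++k) idx[k] = rand_int(n);  // bootstrap
    Builder bld(X, y, g, mtry, min_node);
    bld.build(idx);
    int nn = (int)bld.tree.feat.size();
    NumericMatrix pm(nn, g);
    for (int v = 0; v < nn; ++v)
      if (bld.tree.feat[v] < 0)
        for (int c = 0; c < g; ++c) pm(v, c) = bld.tree.prob[v][c];
    forest[b] = List::create(_["feat"] = wrap(bld.tree.feat),
                             _["thr"] = wrap(bld.tree.thr),
                             _["left"] = wrap(bld.tree.left),
                             _["right"] = wrap(bld.tree.right),
                             _["prob"] = pm);
  }
  return forest;
}

// [[Rcpp::export]]
NumericMatrix rf_predict_cpp(List forest, NumericMatrix X, int g) {
  int n = X.nrow(), ntree = forest.size();
  NumericMatrix out(n, g);
  for (int b = 0; b < ntree; ++b) {
    List tr = forest[b];
    IntegerVector feat = tr["feat"], left = tr["left"], right = tr["right"];
    NumericVector thr = tr["thr"];
    NumericMatrix prob = tr["prob"];
    for (int i = 0; i < n; ++i) {
      int v = 0;
      while (feat[v] >= 0)
        v = (X(i, feat[v]) <= thr[v]) ? left[v] : right[v];
      for (int c = 0; c < g; ++c) out(i, c) += prob(v, c);
    }
  }
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < g; ++c) out(i, c) /= ntree;
  return out;
}
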