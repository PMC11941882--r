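// Regression-tree ensembles used by the consensus feature-selection pipeline.
// A compact CART core (exhaustive weighted-SSE split search) backs three
// learners: bagged random forest (with impurity importance, also used by the
// Boruta ranker), squared-loss gradient boosting, and AdaBoost.R2.
// All randomness flows through a fully specified mt19937 stream so results
// are reproducible across platforms; std:: distributions are avoided because
// their output is implementation-defined.

#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct Node {
  int feat;      // -1 for leaf
  double thr;    // split threshold (go left if x <= thr)
  double value;  // leaf prediction
  int left, right;
};

typedef std::vector<Node> Tree;

inline double unif01(std::mt19937 &gen) {
  // 53-bit uniform in [0,1), platform-stable
  uint64_t hi = gen() >> 5, lo = gen() >> 6;
  return (hi * 67108864.0 + lo) * (1.0 / 9007199254740992.0);
}

inline int unif_int(std::mt19937 &gen, int n) {
  return static_cast<int>(unif01(gen) * n) % n;
}

struct GrowCtx {
  const double *X;  // column-major n x p
  const double *y;
  const double *w;
  int n, p;
  int mtry, min_split, max_depth;
  std::mt19937 *gen;
  std::vector<double> *importance;  // accumulated weighted SSE decrease
};

int grow(GrowCtx &ctx, Tree &tree, std::vector<int> &idx, int depth) {
  const int m = static_cast<int>(idx.size());
  double W = 0.0, S = 0.0, Q = 0.0;
  for (int i = 0; i < m; ++i) {
    const double wi = ctx.w[idx[i]], yi = ctx.y[idx[i]];
    W += wi; S += wi * yi; Q += wi * yi * yi;
  }
  const double node_val = S / W;
  const double node_sse = Q - S * S / W;

  Node nd; nd.feat = -1; nd.thr = 0.0; nd.value = node_val; nd.left = nd.right = -1;
  const int self = static_cast<int>(tree.size());
  tree.push_back(nd);

  if (depth >= ctx.max_depth || m < ctx.min_split || node_sse <= 1e-12)
    return self;

  // sample mtry candidate features without replacement
  std::vector<int> feats(ctx.p);
  for (int f = 0; f < ctx.p; ++f) feats[f] = f;
  int ncand = std::min(ctx.mtry, ctx.p);
  for (int f = 0; f < ncand; ++f) {
    int j = f + unif_int(*ctx.gen, ctx.p - f);
    std::swap(feats[f], feats[j]);
  }

  double best_sse = node_sse - 1e-12;
  int best_feat = -1, best_pos = -1;
  double best_thr = 0.0;
  std::vector<int> ord(idx);
  std::vector<int> best_ord;

  for (int c = 0; c < ncand; ++c) {
    const int f = feats[c];
    const double *xf = ctx.X + static_cast<size_t>(f) * ctx.n;
    std::sort(ord.begin(), ord.end(),
              [xf](int a, int b) { return xf[a] < xf[b]; });
    double Wl = 0.0, Sl = 0.0, Ql = 0.0;
    for (int i = 0; i < m - 1; ++i) {
      const double wi = ctx.w[ord[i]], yi = ctx.y[ord[i]];
      Wl += wi; Sl += wi * yi; Ql += wi * yi * yi;
      if (xf[ord[i]] == xf[ord[i + 1]]) continue;
      const double Wr = W - Wl, Sr = S - Sl, Qr = Q - Ql;
      if (Wl <= 0.0 || Wr <= 0.0) continue;
      const double sse = (Ql - Sl * Sl / Wl) + (Qr - Sr * Sr / Wr);
      if (sse < best_sse) {
        best_sse = sse; best_feat = f; best_pos = i;
        best_thr = 0.5 * (xf[ord[i]] + xf[ord[i + 1]]);
        best_ord = ord;
      }
    }
  }

  if (best_feat < 0) return self;

  (*ctx.importance)[best_feat] += node_sse - best_sse;
  std::vector<int> lidx(best_ord.begin(), best_ord.begin() + best_pos + 1);
  std::vector<int> ridx(best_ord.begin() + best_pos + 1, best_ord.end());
  tree[self].feat = best_feat;
  tree[self].thr = best_thr;
  tree[self].left = grow(ctx, tree, lidx, depth + 1);
  tree[self].right = grow(ctx, tree, ridx, depth + 1);
  return self;
}

double predict_one(const Tree &tree, const double *xrow, int n, int p) {
  (void)p;
  int node = 0;
  while (tree[node].feat >= 0) {
    const double v = xrow[static_cast<size_t>(tree[node].feat) * n];
    node = (v <= tree[node].thr) ? tree[node].left : tree[node].right;
  }
  return tree[node].value;
}

void predict_tree(const Tree &tree, const NumericMatrix &X, std::vector<double> &out) {
  const int n = X.nrow(), p = X.ncol();
  out.resize(n);
  for (int i = 0; i < n; ++i) out[i] = predict_one(tree, &X[0] + i, n, p);
}

Tree fit_tree(const NumericMatrix &X, const std::vector<double> &y,
              const std::vector<double> &w, const std::vector<int> &idx,
              int mtry, int min_split, int max_depth, std::mt19937 &gen,
              std::vector<double> &importance) {
  GrowCtx ctx;
  ctx.X = &X[0]; ctx.y = y.data(); ctx.w = w.data();
  ctx.n = X.nrow(); ctx.p = X.ncol();
  ctx.mtry = mtry; ctx.min_split = min_split; ctx.max_depth = max_depth;
  ctx.gen = &gen; ctx.importance = &importance;
  Tree tree;
  std::vector<int> root(idx);
  grow(ctx, tree, root, 0);
  return tree;
}

}  // namespace

//' @noRd
// [[Rcpp::export]]
List cpp_rf(NumericMatrix Xtr, NumericVector ytr, NumericMatrix Xte,
            int ntree, int mtry, int min_split, int max_depth, int seed) {
  const int n = Xtr.nrow(), p = Xtr.ncol(), nte = Xte.nrow();
  std::mt19937 gen(static_cast<uint32_t>(seed));
  std::vector<double> y(ytr.begin(), ytr.end());
  std::vector<double> w(n, 1.0);
  std::vector<double> importance(p, 0.0);
  std::vector<double> pred(nte, 0.0), tp;

  for (int b = 0; b < ntree; ++b) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = unif_int(gen, n);
    Tree tree = fit_tree(Xtr, y, w, idx, mtry, min_split, max_depth, gen, importance);
    if (nte > 0) {
      predict_tree(tree, Xte, tp);
      for (int i = 0; i < nte; ++i) pred[i] += tp[i];
    }
  }
  if (nte > 0)
    for (int i = 0; i < nte; ++i) pred[i] /= ntree;
  for (int f = 0; f < p; ++f) importance[f] /= ntree;

  return List::create(_["pred"] = NumericVector(pred.begin(), pred.end()),
                      _["importance"] = NumericVector(importance.begin(), importance.end()));
}

//' @noRd
// [[Rcpp::export]]
NumericVector cpp_gbm(NumericMatrix Xtr, NumericVector ytr, NumericMatrix Xte,
                      int nrounds, int max_depth, double learning_rate,
                      double subsample, int min_split, int seed) {
  const int n = Xtr.nrow(), p = Xtr.ncol(), nte = Xte.nrow();
  std::mt19937 gen(static_cast<uint32_t>(seed));
  std::vector<double> w(n, 1.0), importance(p, 0.0);
  const double y0 = mean(ytr);
  std::vector<double> resid(n), fit_tr(n, y0), pred(nte, y0), tp;
  std::vector<int> all(n);
  for (int i = 0; i < n; ++i) all[i] = i;

  const int nsub = std::max(2, static_cast<int>(std::floor(subsample * n)));
  for (int t = 0; t < nrounds; ++t) {
    for (int i = 0; i < n; ++i) resid[i] = ytr[i] - fit_tr[i];
    std::vector<int> idx;
    if (subsample < 1.0) {
      std::vector<int> perm(all);
      for (int i = 0; i < nsub; ++i) {
        int j = i + unif_int(gen, n - i);
        std::swap(perm[i], perm[j]);
      }
      idx.assign(perm.begin(), perm.begin() + nsub);
    } else {
      idx = all;
    }
    Tree tree = fit_tree(Xtr, resid, w, idx, p, min_split, max_depth, gen, importance);
    predict_tree(tree, Xtr, tp);
    for (int i = 0; i < n; ++i) fit_tr[i] += learning_rate * tp[i];
    if (nte > 0) {
      predict_tree(tree, Xte, tp);
      for (int i = 0; i < nte; ++i) pred[i] += learning_rate * tp[i];
    }
  }
  return NumericVector(pred.begin(), pred.end());
}

//' @noRd
// [[Rcpp::export]]
NumericVector cpp_adaboost(NumericMatrix Xtr, NumericVector ytr, NumericMatrix Xte,
                           int n_estimators, int max_depth, int min_split, int seed) {
  // AdaBoost.R2 (linear loss, weighted-median combination)
  const int n = Xtr.nrow(), p = Xtr.ncol(), nte = Xte.nrow();
  std::mt19937 gen(static_cast<uint32_t>(seed));
  std::vector<double> y(ytr.begin(), ytr.end());
  std::vector<double> w(n, 1.0 / n), importance(p, 0.0);
  std::vector<int> all(n);
  for (int i = 0; i < n; ++i) all[i] = i;

  std::vector<std::vector<double> > preds;  // per estimator, test predictions
  std::vector<double> alphas;
  std::vector<double> tp_tr, tp_te;

  for (int t = 0; t < n_estimators; ++t) {
    Tree tree = fit_tree(Xtr, y, w, all, p, min_split, max_depth, gen, importance);
    predict_tree(tree, Xtr, tp_tr);
    double max_err = 0.0;
    for (int i = 0; i < n; ++i)
      max_err = std::max(max_err, std::fabs(tp_tr[i] - y[i]));
    predict_tree(tree, Xte, tp_te);
    if (max_err <= 1e-12) {  // perfect fit: keep and stop
      preds.push_back(tp_te);
      alphas.push_back(std::log(1e12));
      break;
    }
    double L = 0.0;
    for (int i = 0; i < n; ++i)
      L += w[i] * std::fabs(tp_tr[i] - y[i]) / max_err;
    if (L >= 0.5) {
      if (preds.empty()) { preds.push_back(tp_te); alphas.push_back(1.0); }
      break;
    }
    const double beta = std::max(L / (1.0 - L), 1e-12);
    preds.push_back(tp_te);
    alphas.push_back(std::log(1.0 / beta));
    double wsum = 0.0;
    for (int i = 0; i < n; ++i) {
      const double li = std::fabs(tp_tr[i] - y[i]) / max_err;
      w[i] *= std::pow(beta, 1.0 - li);
      wsum += w[i];
    }
    for (int i = 0; i < n; ++i) w[i] /= wsum;
  }

  // weighted median across estimators, per test point
  const int T = static_cast<int>(preds.size());
  NumericVector out(nte);
  const double half = 0.5 * std::accumulate(alphas.begin(), alphas.end(), 0.0);
  std::vector<int> ordT(T);
  for (int i = 0; i < nte; ++i) {
    for (int t = 0; t < T; ++t) ordT[t] = t;
    std::sort(ordT.begin(), ordT.end(),
              [&](int a, int b) { return preds[a][i] < preds[b][i]; });
    double acc = 0.0;
    int chosen = ordT[T - 1];
    for (int t = 0; t < T; ++t) {
      acc += alphas[ordT[t]];
      if (acc >= half) { chosen = ordT[t]; break; }
    }
    out[i] = preds[chosen][i];
  }
  return out;
}

//' @noRd
// [[Rcpp::export]]
NumericVector cpp_rf_importance(NumericMatrix X, NumericVector y,
                                int ntree, int mtry, int min_split,
                                int max_depth, int seed) {
  NumericMatrix empty(0, X.ncol());
  List fit = cpp_rf(X, y, empty, ntree, mtry, min_split, max_depth, seed);
  return fit["importance"];
}
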