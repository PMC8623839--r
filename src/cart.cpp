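// Core compiled routines: CART induction, tree routing/prediction, SER/STRUT
// tree surgery, STRUT threshold selection, and sliding-window feature
// extraction.  Trees cross the R/C++ boundary as flat node tables:
//   feature   int  [n]  1-based split column, 0 = leaf
//   threshold dbl  [n]  split value (x <= threshold goes left), 0 at leaves
//   left,right int [n]  1-based child node ids, 0 at leaves
//   counts    dbl  [n x K]  per-node training class counts
// Node 1 is the root, children carry larger ids than their parent.  The
// left-branch rule is `<=` everywhere; this file is the single source of
// truth for it.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct Node {
  int feature;      // 0-based split column, -1 = leaf
  double threshold;
  int left, right;  // 0-based node ids, -1 = none
  std::vector<double> counts;
  Node(int K) : feature(-1), threshold(0.0), left(-1), right(-1), counts(K, 0.0) {}
};

struct TreeView {
  IntegerVector feature, left, right;
  NumericVector threshold;
  NumericMatrix counts;
  int n, K;
  explicit TreeView(const List& tree)
      : feature(as<IntegerVector>(tree["feature"])),
        left(as<IntegerVector>(tree["left"])),
        right(as<IntegerVector>(tree["right"])),
        threshold(as<NumericVector>(tree["threshold"])),
        counts(as<NumericMatrix>(tree["counts"])) {
    n = feature.size();
    K = counts.ncol();
  }
  bool is_leaf(int v) const { return feature[v] == 0; }
  int descend(const NumericMatrix& X, int i) const {
    int v = 0;
    while (!is_leaf(v)) {
      double x = X(i, feature[v] - 1);
      v = (x <= threshold[v]) ? (left[v] - 1) : (right[v] - 1);
    }
    return v;
  }
  int leaf_class(int v) const {
    int best = 0;
    double bc = counts(v, 0);
    for (int k = 1; k < K; ++k)
      if (counts(v, k) > bc) { bc = counts(v, k); best = k; }
    return best;  // ties -> lowest class index
  }
};

List nodes_to_list(const std::vector<Node>& nodes, int K) {
  int n = nodes.size();
  IntegerVector feature(n), left(n), right(n);
  NumericVector threshold(n);
  NumericMatrix counts(n, K);
  for (int i = 0; i < n; ++i) {
    feature[i] = nodes[i].feature + 1;   // 0 marks a leaf
    threshold[i] = nodes[i].threshold;
    left[i] = nodes[i].left + 1;
    right[i] = nodes[i].right + 1;
    for (int k = 0; k < K; ++k) counts(i, k) = nodes[i].counts[k];
  }
  return List::create(_["feature"] = feature, _["threshold"] = threshold,
                      _["left"] = left, _["right"] = right, _["counts"] = counts);
}

// ---------------------------------------------------------------- induction
//
// Presorted weighted CART.  Rows enter with a multiplicity weight (bootstrap
// count); per feature, the ids of the in-bag rows are kept sorted by feature
// value in one flat array (d slices of length m).  A split partitions every
// slice stably in place, so children inherit sorted order and no per-node
// sorting is needed.  Candidate thresholds are midpoints between consecutive
// distinct values; the Gini criterion is evaluated via the identity
// impurity-weighted-children  ~  -(sum_k nL_k^2 / nL + sum_k nR_k^2 / nR).

struct GrowTask {
  int parent;  // -1 for root
  int s, e;    // range in the sorted slices
  bool is_left;
  std::vector<double> counts;  // class counts of this node's rows
};

struct BestSplit {
  bool found;
  int feature;
  double threshold, score;
  std::vector<double> left_counts;  // class counts of the left child
};


// Per-node-sort growth for small nodes: one shared row array with range
// tasks instead of d presorted slices.  Split semantics, tie rules and the
// per-node RNG draw order are identical to the slice-based path; only the
// bookkeeping differs.
struct SmallScratch {
  std::vector<int> rows, tmp;
  std::vector<std::pair<double, int> > pr;
};

void small_grow(std::vector<Node>& out, const NumericMatrix& X,
                const IntegerVector& y, int K, int mtry,
                const std::vector<double>& w, std::vector<int>& feats,
                SmallScratch& sc, int s0, int e0, int parent0, bool left0) {
  const int d = X.ncol();
  const R_xlen_t nX = X.nrow();
  const double* Xp = &X(0, 0);
  const bool sample_feats = mtry < d;
  std::vector<double> cl(K), cr(K);
  std::vector<GrowTask> stack;
  GrowTask t0; t0.parent = parent0; t0.s = s0; t0.e = e0; t0.is_left = left0;
  stack.push_back(t0);
  while (!stack.empty()) {
    GrowTask t = stack.back();
    stack.pop_back();
    const int me = out.size();
    out.push_back(Node(K));
    if (t.parent >= 0) {
      if (t.is_left) out[t.parent].left = me; else out[t.parent].right = me;
    }
    const int n = t.e - t.s;
    double ntot = 0.0;
    {
      std::vector<double>& cnt = out[me].counts;
      for (int i = t.s; i < t.e; ++i) cnt[y[sc.rows[i]]] += w[sc.rows[i]];
      for (int k = 0; k < K; ++k) ntot += cnt[k];
    }
    int present = 0;
    for (int k = 0; k < K; ++k) if (out[me].counts[k] > 0) ++present;
    if (present <= 1 || n < 2) continue;

    double parent_sq = 0.0;
    for (int k = 0; k < K; ++k) parent_sq += out[me].counts[k] * out[me].counts[k];
    parent_sq /= ntot;

    int nf = sample_feats ? mtry : d;
    if (sample_feats) {
      for (int i = 0; i < nf; ++i) {
        int j = i + (int)(unif_rand() * (d - i));
        if (j >= d) j = d - 1;
        std::swap(feats[i], feats[j]);
      }
    }
    BestSplit best; best.found = false; best.score = 0.0;
    for (int fi = 0; fi < nf; ++fi) {
      const int f = sample_feats ? feats[fi] : fi;
      const double* xcol = Xp + (size_t)f * nX;
      sc.pr.resize(n);
      for (int i = 0; i < n; ++i) {
        const int r = sc.rows[t.s + i];
        sc.pr[i] = std::make_pair(xcol[r], r);
      }
      std::sort(sc.pr.begin(), sc.pr.end());
      std::fill(cl.begin(), cl.end(), 0.0);
      std::copy(out[me].counts.begin(), out[me].counts.end(), cr.begin());
      double sl = 0.0, sr = 0.0, wl = 0.0;
      for (int k = 0; k < K; ++k) sr += cr[k] * cr[k];
      for (int i = 0; i < n - 1; ++i) {
        const int r = sc.pr[i].second;
        const int c = y[r];
        const double wi = w[r];
        sl += wi * (2.0 * cl[c] + wi);
        sr += wi * (-2.0 * cr[c] + wi);
        cl[c] += wi; cr[c] -= wi; wl += wi;
        const double xv = sc.pr[i].first, xn = sc.pr[i + 1].first;
        if (xv == xn) continue;
        const double score = sl / wl + sr / (ntot - wl);
        double thr = xv + 0.5 * (xn - xv);
        if (thr <= xv) thr = xv;
        if (!best.found || score > best.score + 1e-12) {
          best.found = true; best.feature = f; best.threshold = thr;
          best.score = score; best.left_counts = cl;
        }
      }
    }
    if (!best.found || best.score <= parent_sq + 1e-9) continue;

    const double* xb = Xp + (size_t)best.feature * nX;
    sc.tmp.clear();
    int p = t.s;
    for (int i = t.s; i < t.e; ++i) {
      const int r = sc.rows[i];
      if (xb[r] <= best.threshold) sc.rows[p++] = r; else sc.tmp.push_back(r);
    }
    const int nl = p - t.s;
    std::copy(sc.tmp.begin(), sc.tmp.end(), sc.rows.begin() + p);
    out[me].feature = best.feature;
    out[me].threshold = best.threshold;
    GrowTask tr_; tr_.parent = me; tr_.s = t.s + nl; tr_.e = t.e; tr_.is_left = false;
    GrowTask tl_; tl_.parent = me; tl_.s = t.s; tl_.e = t.s + nl; tl_.is_left = true;
    stack.push_back(tr_);
    stack.push_back(tl_);
  }
}

int engine_grow(std::vector<Node>& out, const NumericMatrix& X,
                const IntegerVector& y, int K, int mtry,
                const std::vector<double>& w, std::vector<int>& sorted,
                int m) {
  const int d = X.ncol();
  const R_xlen_t nX = X.nrow();
  const double* Xp = &X(0, 0);
  if (m == 0) return -1;
  std::vector<int> tmp(m);
  std::vector<char> side(X.nrow(), 0);
  std::vector<int> feats(d);
  for (int f = 0; f < d; ++f) feats[f] = f;
  std::vector<double> cl(K), cr(K);
  const bool sample_feats = mtry < d;
  SmallScratch sc;
  int root = -1;

  std::vector<GrowTask> stack;
  GrowTask t0; t0.parent = -1; t0.s = 0; t0.e = m; t0.is_left = false;
  t0.counts.assign(K, 0.0);
  for (int i = 0; i < m; ++i) t0.counts[y[sorted[i]]] += w[sorted[i]];
  stack.push_back(std::move(t0));
  const int small_cut = (mtry < d) ? 96 : 0;
  const bool pass_counts = true;
  while (!stack.empty()) {
    GrowTask t = std::move(stack.back());
    stack.pop_back();
    if (t.e - t.s <= small_cut && t.parent >= 0) {
      sc.rows.assign(sorted.begin() + t.s, sorted.begin() + t.e);
      small_grow(out, X, y, K, mtry, w, feats, sc, 0, t.e - t.s,
                 t.parent, t.is_left);
      continue;
    }
    const int me = out.size();
    out.push_back(Node(K));
    if (t.parent >= 0) {
      if (t.is_left) out[t.parent].left = me; else out[t.parent].right = me;
    } else {
      root = me;
    }
    double ntot = 0.0;
    {
      std::vector<double>& cnt = out[me].counts;
      if (!t.counts.empty()) {
        cnt = t.counts;
      } else {
        for (int i = t.s; i < t.e; ++i) cnt[y[sorted[i]]] += w[sorted[i]];
      }
      for (int k = 0; k < K; ++k) ntot += cnt[k];
    }
    int present = 0;
    for (int k = 0; k < K; ++k) if (out[me].counts[k] > 0) ++present;
    if (present <= 1 || t.e - t.s < 2) continue;  // pure or indivisible

    double parent_sq = 0.0;
    for (int k = 0; k < K; ++k) parent_sq += out[me].counts[k] * out[me].counts[k];
    parent_sq /= ntot;

    int nf = sample_feats ? mtry : d;
    if (sample_feats) {  // partial Fisher-Yates through R's RNG
      for (int i = 0; i < nf; ++i) {
        int j = i + (int)(unif_rand() * (d - i));
        if (j >= d) j = d - 1;
        std::swap(feats[i], feats[j]);
      }
    }
    BestSplit best; best.found = false; best.score = 0.0;
    for (int fi = 0; fi < nf; ++fi) {
      const int f = sample_feats ? feats[fi] : fi;
      const int* arr = &sorted[(size_t)f * m];
      const double* xcol = Xp + (size_t)f * nX;
      std::fill(cl.begin(), cl.end(), 0.0);
      std::copy(out[me].counts.begin(), out[me].counts.end(), cr.begin());
      double sl = 0.0, sr = 0.0, wl = 0.0;
      for (int k = 0; k < K; ++k) sr += cr[k] * cr[k];
      for (int i = t.s; i < t.e - 1; ++i) {
        const int r = arr[i];
        const int c = y[r];
        const double wi = w[r];
        sl += wi * (2.0 * cl[c] + wi);
        sr += wi * (-2.0 * cr[c] + wi);
        cl[c] += wi; cr[c] -= wi; wl += wi;
        const double xv = xcol[r], xn = xcol[arr[i + 1]];
        if (xv == xn) continue;
        const double score = sl / wl + sr / (ntot - wl);
        double thr = xv + 0.5 * (xn - xv);
        if (thr <= xv) thr = xv;  // guard against denormal gaps
        // ties: keep earlier feature (scan order), then smaller threshold
        if (!best.found || score > best.score + 1e-12) {
          best.found = true; best.feature = f; best.threshold = thr;
          best.score = score; best.left_counts = cl;
        }
      }
    }
    if (!best.found || best.score <= parent_sq + 1e-9) continue;  // no gain

    {
      const double* xb = Xp + (size_t)best.feature * nX;
      for (int i = t.s; i < t.e; ++i) {
        const int r = sorted[i];
        side[r] = xb[r] <= best.threshold ? 0 : 1;
      }
    }
    int nl = 0;
    for (int f = 0; f < d; ++f) {
      int* arr = &sorted[(size_t)f * m];
      int p = 0;
      for (int i = t.s; i < t.e; ++i) if (!side[arr[i]]) tmp[p++] = arr[i];
      nl = p;
      for (int i = t.s; i < t.e; ++i) if (side[arr[i]]) tmp[p++] = arr[i];
      std::copy(tmp.begin(), tmp.begin() + (t.e - t.s), arr + t.s);
    }
    out[me].feature = best.feature;
    out[me].threshold = best.threshold;
    // left child first (depth-first), right task deferred
    GrowTask tr_; tr_.parent = me; tr_.s = t.s + nl; tr_.e = t.e; tr_.is_left = false;
    if (pass_counts && t.e - (t.s + nl) > small_cut) {
      tr_.counts.resize(K);
      for (int k = 0; k < K; ++k) {
        tr_.counts[k] = out[me].counts[k] - best.left_counts[k];
      }
    }
    GrowTask tl_; tl_.parent = me; tl_.s = t.s; tl_.e = t.s + nl; tl_.is_left = true;
    if (pass_counts && nl > small_cut) tl_.counts = std::move(best.left_counts);
    stack.push_back(std::move(tr_));
    stack.push_back(std::move(tl_));
  }
  return root;
}

// Sorted slices for an explicit row set (weights all from `rows`).
void build_sorted(const NumericMatrix& X, const std::vector<int>& uniq,
                  std::vector<int>& sorted) {
  const int d = X.ncol(), m = uniq.size();
  sorted.resize((size_t)d * m);
  const double* Xp = &X(0, 0);
  const R_xlen_t nX = X.nrow();
  for (int f = 0; f < d; ++f) {
    int* arr = &sorted[(size_t)f * m];
    const double* xcol = Xp + (size_t)f * nX;
    std::copy(uniq.begin(), uniq.end(), arr);
    std::sort(arr, arr + m, [&](int a, int b) {
      if (xcol[a] != xcol[b]) return xcol[a] < xcol[b];
      return a < b;  // deterministic tie order
    });
  }
}

// Grow a tree from an arbitrary (possibly duplicated) row list.
int grow_from_rows(std::vector<Node>& out, const NumericMatrix& X,
                   const IntegerVector& y, int K, int mtry,
                   const std::vector<int>& rows) {
  bool pure = true;
  for (size_t i = 1; i < rows.size(); ++i) {
    if (y[rows[i]] != y[rows[0]]) { pure = false; break; }
  }
  if (rows.size() < 2 || pure) {
    const int me = out.size();
    out.push_back(Node(K));
    for (size_t i = 0; i < rows.size(); ++i) out[me].counts[y[rows[i]]] += 1.0;
    return me;
  }
  std::vector<double> w(X.nrow(), 0.0);
  for (size_t i = 0; i < rows.size(); ++i) w[rows[i]] += 1.0;
  std::vector<int> uniq;
  uniq.reserve(rows.size());
  for (int r = 0; r < X.nrow(); ++r) if (w[r] > 0) uniq.push_back(r);
  std::vector<int> sorted;
  build_sorted(X, uniq, sorted);
  return engine_grow(out, X, y, K, mtry, w, sorted, uniq.size());
}

}  // namespace

// [[Rcpp::export]]
List cpp_induce_tree(NumericMatrix X, IntegerVector y, int K, int mtry,
                     IntegerVector rows1) {
  std::vector<int> rows(rows1.size());
  for (int i = 0; i < rows1.size(); ++i) rows[i] = rows1[i] - 1;
  std::vector<Node> nodes;
  grow_from_rows(nodes, X, y, K, mtry, rows);
  return nodes_to_list(nodes, K);
}

// Train a full forest sharing one global presort across trees; bootstrap
// draws come from R's RNG, so the result is deterministic under set.seed().
// [[Rcpp::export]]
List cpp_train_forest(NumericMatrix X, IntegerVector y, int K, int mtry,
                      int n_trees, bool bootstrap) {
  const int n = X.nrow(), d = X.ncol();
  std::vector<int> global((size_t)d * n);
  const double* Xp = &X(0, 0);
  for (int f = 0; f < d; ++f) {
    int* arr = &global[(size_t)f * n];
    const double* xcol = Xp + (size_t)f * n;
    for (int i = 0; i < n; ++i) arr[i] = i;
    std::sort(arr, arr + n, [&](int a, int b) {
      if (xcol[a] != xcol[b]) return xcol[a] < xcol[b];
      return a < b;
    });
  }
  List forest(n_trees);
  std::vector<double> w(n);
  std::vector<int> sorted;
  for (int t = 0; t < n_trees; ++t) {
    int m = n;
    if (bootstrap) {
      std::fill(w.begin(), w.end(), 0.0);
      for (int i = 0; i < n; ++i) {
        int r = (int)(unif_rand() * n);
        if (r >= n) r = n - 1;
        w[r] += 1.0;
      }
      m = 0;
      for (int r = 0; r < n; ++r) if (w[r] > 0) ++m;
      sorted.resize((size_t)d * m);
      for (int f = 0; f < d; ++f) {
        const int* ga = &global[(size_t)f * n];
        int* slice = &sorted[(size_t)f * m];
        int p = 0;
        for (int i = 0; i < n; ++i) if (w[ga[i]] > 0) slice[p++] = ga[i];
      }
    } else {
      std::fill(w.begin(), w.end(), 1.0);
      sorted.assign(global.begin(), global.end());
    }
    std::vector<Node> nodes;
    engine_grow(nodes, X, y, K, mtry, w, sorted, m);
    forest[t] = nodes_to_list(nodes, K);
  }
  return forest;
}

// [[Rcpp::export]]
IntegerVector cpp_tree_leaf(List tree, NumericMatrix X) {
  TreeView t(tree);
  IntegerVector out(X.nrow());
  for (int i = 0; i < X.nrow(); ++i) out[i] = t.descend(X, i) + 1;
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_tree_predict(List tree, NumericMatrix X) {
  TreeView t(tree);
  IntegerVector out(X.nrow());
  for (int i = 0; i < X.nrow(); ++i) out[i] = t.leaf_class(t.descend(X, i));
  return out;  // 0-based class indices
}

// Per-tree votes: rows x trees matrix of 0-based class indices.
// [[Rcpp::export]]
IntegerMatrix cpp_forest_votes(List trees, NumericMatrix X) {
  const int T = trees.size(), n = X.nrow();
  IntegerMatrix votes(n, T);
  for (int j = 0; j < T; ++j) {
    TreeView t(as<List>(trees[j]));
    for (int i = 0; i < n; ++i) votes(i, j) = t.leaf_class(t.descend(X, i));
  }
  return votes;
}

// Majority over vote columns; ties -> lowest class index.
// [[Rcpp::export]]
IntegerVector cpp_majority_vote(IntegerMatrix votes, int K) {
  const int n = votes.nrow(), T = votes.ncol();
  IntegerVector out(n);
  std::vector<int> tally(K);
  for (int i = 0; i < n; ++i) {
    std::fill(tally.begin(), tally.end(), 0);
    for (int j = 0; j < T; ++j) ++tally[votes(i, j)];
    int best = 0;
    for (int k = 1; k < K; ++k) if (tally[k] > tally[best]) best = k;
    out[i] = best;
  }
  return out;
}

// ---------------------------------------------------------------- SER

namespace {

struct SerCtx {
  const NumericMatrix& X;
  const IntegerVector& y;
  int K;
  std::vector<Node> out;
  SerCtx(const NumericMatrix& X_, const IntegerVector& y_, int K_)
      : X(X_), y(y_), K(K_) {}
};

// Flat copy of the subtree rooted at v (no target rows reach it, so its
// structure and source counts are preserved verbatim).
int ser_copy_subtree(SerCtx& ctx, const TreeView& src, int v0) {
  struct CopyTask { int src_v, parent; bool is_left; };
  int root_new = -1;
  std::vector<CopyTask> st;
  CopyTask c0; c0.src_v = v0; c0.parent = -1; c0.is_left = false;
  st.push_back(c0);
  while (!st.empty()) {
    CopyTask t = st.back();
    st.pop_back();
    const int me = ctx.out.size();
    ctx.out.push_back(Node(ctx.K));
    ctx.out[me].feature = src.feature[t.src_v] - 1;
    ctx.out[me].threshold = src.threshold[t.src_v];
    for (int k = 0; k < ctx.K; ++k) {
      ctx.out[me].counts[k] = src.counts(t.src_v, k);
    }
    if (t.parent >= 0) {
      if (t.is_left) ctx.out[t.parent].left = me;
      else ctx.out[t.parent].right = me;
    } else {
      root_new = me;
    }
    if (!src.is_leaf(t.src_v)) {
      CopyTask r; r.src_v = src.right[t.src_v] - 1; r.parent = me; r.is_left = false;
      CopyTask l; l.src_v = src.left[t.src_v] - 1; l.parent = me; l.is_left = true;
      st.push_back(r);
      st.push_back(l);
    }
  }
  return root_new;
}

// Copy-and-expand: returns new node id in ctx.out; rows = target rows at node.
int ser_expand(SerCtx& ctx, const TreeView& src, int v, std::vector<int>& rows) {
  if (rows.empty()) return ser_copy_subtree(ctx, src, v);
  if (src.is_leaf(v)) {
    // expansion: full CART (all features, no bootstrap) on the routed rows
    return grow_from_rows(ctx.out, ctx.X, ctx.y, ctx.K, ctx.X.ncol(), rows);
  }
  int me = ctx.out.size();
  ctx.out.push_back(Node(ctx.K));
  ctx.out[me].feature = src.feature[v] - 1;
  ctx.out[me].threshold = src.threshold[v];
  for (size_t i = 0; i < rows.size(); ++i) {
    ctx.out[me].counts[ctx.y[rows[i]]] += 1.0;
  }
  std::vector<int> li, ri;
  for (size_t i = 0; i < rows.size(); ++i) {
    double x = ctx.X(rows[i], src.feature[v] - 1);
    (x <= src.threshold[v] ? li : ri).push_back(rows[i]);
  }
  { std::vector<int> t; rows.swap(t); }
  int l = ser_expand(ctx, src, src.left[v] - 1, li);
  ctx.out[me].left = l;
  int r = ser_expand(ctx, src, src.right[v] - 1, ri);
  ctx.out[me].right = r;
  return me;
}

// Bottom-up reduction (prune iff subtree error > leaf error, strictly).
// Returns the number of target rows misclassified by the (possibly
// collapsed) subtree at v.
double ser_reduce(SerCtx& ctx, int v, const std::vector<int>& rows) {
  if (rows.empty()) return 0.0;  // no data below: nothing to audit or prune
  if (ctx.out[v].feature < 0) {
    const Node& nd = ctx.out[v];
    int best = 0;
    for (int k = 1; k < ctx.K; ++k)
      if (nd.counts[k] > nd.counts[best]) best = k;
    double err = 0.0;
    for (size_t i = 0; i < rows.size(); ++i)
      if (ctx.y[rows[i]] != best) err += 1.0;
    return err;
  }
  std::vector<int> li, ri;
  for (size_t i = 0; i < rows.size(); ++i) {
    double x = ctx.X(rows[i], ctx.out[v].feature);
    (x <= ctx.out[v].threshold ? li : ri).push_back(rows[i]);
  }
  double sub_err = ser_reduce(ctx, ctx.out[v].left, li) +
                   ser_reduce(ctx, ctx.out[v].right, ri);
  if (rows.empty()) return sub_err;
  std::vector<double> cnt(ctx.K, 0.0);
  for (size_t i = 0; i < rows.size(); ++i) cnt[ctx.y[rows[i]]] += 1.0;
  double mx = 0.0;
  for (int k = 0; k < ctx.K; ++k) mx = std::max(mx, cnt[k]);
  double leaf_err = (double)rows.size() - mx;
  if (sub_err > leaf_err) {  // strict: ties keep the subtree
    Node& me = ctx.out[v];
    me.feature = -1; me.left = -1; me.right = -1; me.threshold = 0.0;
    me.counts = cnt;
    return leaf_err;
  }
  return sub_err;
}

// Compact a node vector: drop nodes unreachable from the root, renumber in
// depth-first order (children after parents).
List compact_nodes(const std::vector<Node>& nodes, int K) {
  std::vector<int> map(nodes.size(), -1), order;
  std::vector<int> stack;
  stack.push_back(0);
  while (!stack.empty()) {
    int v = stack.back(); stack.pop_back();
    if (map[v] >= 0) continue;
    map[v] = order.size();
    order.push_back(v);
    if (nodes[v].feature >= 0) {
      stack.push_back(nodes[v].right);
      stack.push_back(nodes[v].left);
    }
  }
  std::vector<Node> out;
  out.reserve(order.size());
  for (size_t i = 0; i < order.size(); ++i) {
    Node nd = nodes[order[i]];
    if (nd.feature >= 0) { nd.left = map[nd.left]; nd.right = map[nd.right]; }
    out.push_back(nd);
  }
  return nodes_to_list(out, K);
}

}  // namespace

// [[Rcpp::export]]
List cpp_ser_tree(List tree, NumericMatrix X, IntegerVector y, int K) {
  TreeView src(tree);
  SerCtx ctx(X, y, K);
  std::vector<int> rows(X.nrow());
  for (int i = 0; i < X.nrow(); ++i) rows[i] = i;
  std::vector<int> rows2(rows);
  ser_expand(ctx, src, 0, rows);
  ser_reduce(ctx, 0, rows2);
  return compact_nodes(ctx.out, K);
}

// ---------------------------------------------------------------- STRUT

namespace {

double jsd2(const std::vector<double>& p, const std::vector<double>& q) {
  double s = 0.0;
  for (size_t k = 0; k < p.size(); ++k) {
    double m = 0.5 * (p[k] + q[k]);
    if (p[k] > 0) s += 0.5 * p[k] * std::log2(p[k] / m);
    if (q[k] > 0) s += 0.5 * q[k] * std::log2(q[k] / m);
  }
  if (s < 0) s = 0;
  if (s > 1) s = 1;
  return s;
}

struct ThrSearch {
  bool ok;
  double threshold, ig, dg, ig_max;
  std::vector<double> cand, cand_ig, cand_dg;
  std::vector<bool> admissible;
};

// Candidates: midpoints of consecutive distinct sorted values.  Admissible
// candidates are IG local maxima (>= both neighbours); among them the one
// maximising DG wins, ties -> smallest threshold.  `want_trace` keeps the
// per-candidate vectors (used by the R-facing wrapper and tests).
ThrSearch search_threshold(const std::vector<double>& values,
                           const std::vector<int>& labels, int K,
                           const std::vector<double>& QL,
                           const std::vector<double>& QR, double min_ig_frac,
                           bool want_trace) {
  ThrSearch res; res.ok = false;
  const int n = values.size();
  std::vector<std::pair<double, int> > buf(n);
  for (int i = 0; i < n; ++i) buf[i] = std::make_pair(values[i], labels[i]);
  std::sort(buf.begin(), buf.end());
  if (buf.front().first == buf.back().first) return res;

  std::vector<double> tot(K, 0.0);
  for (int i = 0; i < n; ++i) tot[buf[i].second] += 1.0;
  double parent_imp = 1.0;
  for (int k = 0; k < K; ++k) parent_imp -= (tot[k] / n) * (tot[k] / n);

  std::vector<double> cand, igs;
  std::vector<std::vector<double> > lcounts;
  std::vector<int> lns;
  std::vector<double> cl(K, 0.0);
  std::vector<double> cr(tot);
  double sl = 0.0, sr = 0.0;
  for (int k = 0; k < K; ++k) sr += cr[k] * cr[k];
  int nl = 0;
  for (int i = 0; i < n - 1; ++i) {
    int c = buf[i].second;
    sl += 2.0 * cl[c] + 1.0;
    sr += -2.0 * cr[c] + 1.0;
    cl[c] += 1.0; cr[c] -= 1.0;
    ++nl;
    if (buf[i].first == buf[i + 1].first) continue;
    int nr = n - nl;
    double impl = 1.0 - sl / ((double)nl * nl);
    double impr = 1.0 - sr / ((double)nr * nr);
    double ig = parent_imp - ((double)nl / n) * impl - ((double)nr / n) * impr;
    double thr = buf[i].first + 0.5 * (buf[i + 1].first - buf[i].first);
    if (thr <= buf[i].first) thr = buf[i].first;
    cand.push_back(thr);
    igs.push_back(ig);
    lcounts.push_back(cl);
    lns.push_back(nl);
  }
  const int m = cand.size();
  if (m == 0) return res;

  res.ok = true;
  res.ig_max = *std::max_element(igs.begin(), igs.end());
  // admissible: IG local maximum that also keeps a meaningful share of the
  // node's maximal IG (tail candidates of a piecewise-constant IG curve are
  // formally local maxima but carry no information)
  const double ig_floor = min_ig_frac * res.ig_max - 1e-12;
  std::vector<bool> adm(m);
  for (int i = 0; i < m; ++i) {
    bool a = igs[i] >= ig_floor;
    if (i > 0 && igs[i] < igs[i - 1]) a = false;
    if (i < m - 1 && igs[i] < igs[i + 1]) a = false;
    adm[i] = a;
  }
  std::vector<double> dgs(m, NA_REAL);
  int best = -1;
  for (int i = 0; i < m; ++i) {
    if (!adm[i] && !want_trace) continue;
    std::vector<double> qhl(K), qhr(K);
    int nlc = lns[i], nrc = n - lns[i];
    for (int k = 0; k < K; ++k) {
      qhl[k] = lcounts[i][k] / nlc;
      qhr[k] = (tot[k] - lcounts[i][k]) / nrc;
    }
    double dg = 1.0 - ((double)nlc / n) * jsd2(QL, qhl) -
                ((double)nrc / n) * jsd2(QR, qhr);
    dgs[i] = dg;
    if (adm[i] && (best < 0 || dg > dgs[best]))
      best = i;  // ties -> smallest threshold (first seen wins)
  }
  res.threshold = cand[best];
  res.ig = igs[best];
  res.dg = dgs[best];
  if (want_trace) {
    res.cand = cand; res.cand_ig = igs; res.cand_dg = dgs;
    res.admissible = adm;
  }
  return res;
}

struct StrutCtx {
  const NumericMatrix& X;
  const IntegerVector& y;
  int K;
  double min_ig_frac;
  std::vector<Node> out;
  std::vector<double> diag_ig, diag_igmax;  // per output node, NA at leaves
  StrutCtx(const NumericMatrix& X_, const IntegerVector& y_, int K_,
           double frac)
      : X(X_), y(y_), K(K_), min_ig_frac(frac) {}
};

int strut_node(StrutCtx& ctx, const TreeView& src, int v, std::vector<int>& rows) {
  if (src.is_leaf(v)) {
    int me = ctx.out.size();
    ctx.out.push_back(Node(ctx.K));
    ctx.diag_ig.push_back(NA_REAL);
    ctx.diag_igmax.push_back(NA_REAL);
    for (size_t i = 0; i < rows.size(); ++i)
      ctx.out[me].counts[ctx.y[rows[i]]] += 1.0;
    return me;
  }
  const int f = src.feature[v] - 1;
  std::vector<double> vals(rows.size());
  for (size_t i = 0; i < rows.size(); ++i) vals[i] = ctx.X(rows[i], f);
  bool constant = true;
  for (size_t i = 1; i < vals.size(); ++i)
    if (vals[i] != vals[0]) { constant = false; break; }
  if (constant) {
    // Degenerate feature: the node cannot separate the target rows.  Route by
    // the source threshold and contract the node to the reachable child; the
    // other branch cannot be reached in the target domain and is pruned.
    int side = (vals[0] <= src.threshold[v]) ? src.left[v] - 1 : src.right[v] - 1;
    return strut_node(ctx, src, side, rows);
  }
  std::vector<int> labs(rows.size());
  for (size_t i = 0; i < rows.size(); ++i) labs[i] = ctx.y[rows[i]];
  // source child distributions QL / QR
  std::vector<double> QL(ctx.K), QR(ctx.K);
  double sL = 0.0, sR = 0.0;
  int lc = src.left[v] - 1, rc = src.right[v] - 1;
  for (int k = 0; k < ctx.K; ++k) { sL += src.counts(lc, k); sR += src.counts(rc, k); }
  for (int k = 0; k < ctx.K; ++k) {
    QL[k] = sL > 0 ? src.counts(lc, k) / sL : 0.0;
    QR[k] = sR > 0 ? src.counts(rc, k) / sR : 0.0;
  }
  ThrSearch ts = search_threshold(vals, labs, ctx.K, QL, QR,
                                  ctx.min_ig_frac, false);
  // (non-constant values guarantee ts.ok)
  int me = ctx.out.size();
  ctx.out.push_back(Node(ctx.K));
  ctx.diag_ig.push_back(ts.ig);
  ctx.diag_igmax.push_back(ts.ig_max);
  ctx.out[me].feature = f;
  ctx.out[me].threshold = ts.threshold;
  for (size_t i = 0; i < rows.size(); ++i) ctx.out[me].counts[ctx.y[rows[i]]] += 1.0;
  std::vector<int> li, ri;
  for (size_t i = 0; i < rows.size(); ++i) {
    (ctx.X(rows[i], f) <= ts.threshold ? li : ri).push_back(rows[i]);
  }
  { std::vector<int> t; rows.swap(t); }
  int l = strut_node(ctx, src, src.left[v] - 1, li);
  ctx.out[me].left = l;
  int r = strut_node(ctx, src, src.right[v] - 1, ri);
  ctx.out[me].right = r;
  return me;
}

}  // namespace

// [[Rcpp::export]]
List cpp_strut_tree(List tree, NumericMatrix X, IntegerVector y, int K,
                    double min_ig_frac) {
  TreeView src(tree);
  StrutCtx ctx(X, y, K, min_ig_frac);
  std::vector<int> rows(X.nrow());
  for (int i = 0; i < X.nrow(); ++i) rows[i] = i;
  strut_node(ctx, src, 0, rows);
  List out = nodes_to_list(ctx.out, K);
  out["diag_ig"] = wrap(ctx.diag_ig);
  out["diag_ig_max"] = wrap(ctx.diag_igmax);
  return out;
}

// [[Rcpp::export]]
List cpp_select_threshold(NumericVector values, IntegerVector labels, int K,
                          NumericVector QL, NumericVector QR,
                          double min_ig_frac) {
  std::vector<double> v(values.begin(), values.end());
  std::vector<int> l(labels.begin(), labels.end());
  std::vector<double> ql(QL.begin(), QL.end()), qr(QR.begin(), QR.end());
  ThrSearch ts = search_threshold(v, l, K, ql, qr, min_ig_frac, true);
  if (!ts.ok) return List::create(_["ok"] = false);
  return List::create(
      _["ok"] = true, _["threshold"] = ts.threshold, _["ig"] = ts.ig,
      _["dg"] = ts.dg, _["ig_max"] = ts.ig_max, _["candidates"] = wrap(ts.cand),
      _["candidate_ig"] = wrap(ts.cand_ig), _["candidate_dg"] = wrap(ts.cand_dg),
      _["admissible"] = wrap(std::vector<int>(ts.admissible.begin(), ts.admissible.end())));
}

// ------------------------------------------------------- window features

// Majority value per window; ties (shared maximum) resolve to 0 (rest).
// [[Rcpp::export]]
IntegerVector cpp_window_majority(IntegerVector v, IntegerVector starts0, int W,
                                  int max_val) {
  const int nw = starts0.size();
  IntegerVector out(nw);
  std::vector<int> tally(max_val + 1);
  for (int w = 0; w < nw; ++w) {
    std::fill(tally.begin(), tally.end(), 0);
    int s = starts0[w];
    for (int i = 0; i < W; ++i) ++tally[v[s + i]];
    int best = 0;
    for (int k = 1; k <= max_val; ++k)
      if (tally[k] > tally[best]) best = k;
    int nmax = 0;
    for (int k = 0; k <= max_val; ++k)
      if (tally[k] == tally[best]) ++nmax;
    out[w] = (nmax > 1) ? 0 : best;
  }
  return out;
}

// MAV | VAR | mDWT feature block per window.  Column layout:
//   [mav ch1..chC | var ch1..chC | ch1: d1..dL, approx | ch2: ... ]
// mDWT: periodized DWT (index wrap), marginal = sum of |coefficients| of each
// detail level (shallow -> deep) then of the final approximation.
// [[Rcpp::export]]
NumericMatrix cpp_window_features(NumericMatrix emg, IntegerVector starts0, int W,
                                  NumericVector lo, NumericVector hi, int levels) {
  const int C = emg.ncol(), nw = starts0.size(), L = lo.size();
  const int per_ch = levels + 1;
  NumericMatrix out(nw, C * (2 + per_ch));
  std::vector<double> buf(W), nxt((W + 1) / 2 + 1);
  for (int w = 0; w < nw; ++w) {
    int s = starts0[w];
    for (int c = 0; c < C; ++c) {
      double mav = 0.0, mean = 0.0;
      for (int i = 0; i < W; ++i) {
        double x = emg(s + i, c);
        buf[i] = x;
        mav += std::fabs(x);
        mean += x;
      }
      mav /= W; mean /= W;
      double ss = 0.0;
      for (int i = 0; i < W; ++i) { double dd = buf[i] - mean; ss += dd * dd; }
      out(w, c) = mav;
      out(w, C + c) = W > 1 ? ss / (W - 1) : 0.0;
      int m = W;
      for (int lev = 0; lev < levels; ++lev) {
        int na = (m + 1) / 2;
        double marg = 0.0;
        for (int k = 0; k < na; ++k) {
          double a = 0.0, dcoef = 0.0;
          for (int j = 0; j < L; ++j) {
            double x = buf[(2 * k + j) % m];
            a += lo[j] * x;
            dcoef += hi[j] * x;
          }
          nxt[k] = a;
          marg += std::fabs(dcoef);
        }
        out(w, 2 * C + c * per_ch + lev) = marg;
        for (int k = 0; k < na; ++k) buf[k] = nxt[k];
        m = na;
      }
      double amarg = 0.0;
      for (int k = 0; k < m; ++k) amarg += std::fabs(buf[k]);
      out(w, 2 * C + c * per_ch + levels) = amarg;
    }
  }
  return out;
}
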