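// Boykov-Kolmogorov max-flow / min-cut for s-t grid graphs.
//
// Specialised solver for the segmentation energies built by build_and_cut():
// two search trees grown from source and sink, augmentation along the path
// found when the trees touch, and orphan adoption after saturation. Terminal
// capacities are folded into a single per-node residual (tr_cap > 0: residual
// from the source; < 0: residual to the sink), which pre-pushes the flow
// min(cap_src, cap_snk) through every node.

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cstdint>

using namespace Rcpp;

namespace {

const int PARENT_NONE = -1;     // free node
const int PARENT_TERMINAL = -2; // root of its tree
const int PARENT_ORPHAN = -3;
const double EPS = 1e-12;

enum Tree : uint8_t { FREE = 0, TREE_S = 1, TREE_T = 2 };

struct BK {
  int n;
  std::vector<int> first, nxt, to; // adjacency: arc pairs (2e, 2e+1)
  std::vector<double> rcap;
  std::vector<double> tr_cap;
  std::vector<uint8_t> tree;
  std::vector<int> parent; // arc from node towards its parent, or marker
  std::vector<int> dist, ts;
  std::queue<int> active, orphans;
  int time_now = 0;
  double flow = 0;

  BK(int n_) : n(n_), first(n_, -1), tr_cap(n_, 0.0), tree(n_, FREE),
               parent(n_, PARENT_NONE), dist(n_, 0), ts(n_, 0) {}

  void add_edge(int u, int v, double cap) {
    to.push_back(v); nxt.push_back(first[u]); rcap.push_back(cap);
    first[u] = (int)to.size() - 1;
    to.push_back(u); nxt.push_back(first[v]); rcap.push_back(cap);
    first[v] = (int)to.size() - 1;
  }

  void init() {
    for (int i = 0; i < n; ++i) {
      if (tr_cap[i] > EPS) {
        tree[i] = TREE_S; parent[i] = PARENT_TERMINAL; dist[i] = 1;
        ts[i] = 0; active.push(i);
      } else if (tr_cap[i] < -EPS) {
        tree[i] = TREE_T; parent[i] = PARENT_TERMINAL; dist[i] = 1;
        ts[i] = 0; active.push(i);
      }
    }
  }

  // residual of the arc that would carry flow parent -> child for a node in
  // tree `t` whose parent arc (child -> parent) is `a`
  inline double parent_residual(int a, uint8_t t) const {
    return (t == TREE_S) ? rcap[a ^ 1] : rcap[a];
  }

  // walk to the root; true iff the chain ends at a terminal
  bool rooted(int j) {
    int d = 0;
    int i = j;
    while (true) {
      if (ts[i] == time_now) { d += dist[i]; break; }
      int p = parent[i];
      if (p == PARENT_TERMINAL) { ++d; break; }
      if (p == PARENT_NONE || p == PARENT_ORPHAN) return false;
      i = to[p];
      ++d;
    }
    // mark the walked chain with the established distance
    int dd = d;
    i = j;
    while (ts[i] != time_now) {
      ts[i] = time_now; dist[i] = dd--;
      int p = parent[i];
      if (p == PARENT_TERMINAL || p == PARENT_NONE || p == PARENT_ORPHAN) break;
      i = to[p];
    }
    return true;
  }

  void augment(int a) { // arc a: S-side node -> T-side node, rcap[a] > EPS
    int u = to[a ^ 1], v = to[a];
    double b = rcap[a];
    // bottleneck over the S side
    for (int i = u;;) {
      int p = parent[i];
      if (p == PARENT_TERMINAL) { b = std::min(b, tr_cap[i]); break; }
      b = std::min(b, rcap[p ^ 1]);
      i = to[p];
    }
    // bottleneck over the T side
    for (int i = v;;) {
      int p = parent[i];
      if (p == PARENT_TERMINAL) { b = std::min(b, -tr_cap[i]); break; }
      b = std::min(b, rcap[p]);
      i = to[p];
    }
    // push
    rcap[a] -= b; rcap[a ^ 1] += b;
    for (int i = u;;) {
      int p = parent[i];
      if (p == PARENT_TERMINAL) {
        tr_cap[i] -= b;
        if (tr_cap[i] <= EPS) { parent[i] = PARENT_ORPHAN; orphans.push(i); }
        break;
      }
      rcap[p ^ 1] -= b; rcap[p] += b;
      if (rcap[p ^ 1] <= EPS) { parent[i] = PARENT_ORPHAN; orphans.push(i); }
      i = to[p];
    }
    for (int i = v;;) {
      int p = parent[i];
      if (p == PARENT_TERMINAL) {
        tr_cap[i] += b;
        if (tr_cap[i] >= -EPS) { parent[i] = PARENT_ORPHAN; orphans.push(i); }
        break;
      }
      rcap[p] -= b; rcap[p ^ 1] += b;
      if (rcap[p] <= EPS) { parent[i] = PARENT_ORPHAN; orphans.push(i); }
      i = to[p];
    }
    flow += b;
  }

  void adopt() {
    while (!orphans.empty()) {
      int i = orphans.front(); orphans.pop();
      if (parent[i] != PARENT_ORPHAN) continue;
      uint8_t t = tree[i];
      int found = PARENT_NONE;
      for (int a = first[i]; a != -1; a = nxt[a]) {
        int j = to[a];
        if (tree[j] != t) continue;
        if (parent_residual(a, t) <= EPS) continue;
        if (parent[j] == PARENT_ORPHAN || parent[j] == PARENT_NONE) continue;
        if (rooted(j)) { found = a; break; }
      }
      if (found != PARENT_NONE) {
        parent[i] = found;
        ts[i] = time_now;
        dist[i] = dist[to[found]] + 1;
      } else {
        // i leaves its tree; neighbours may gain work, children are orphaned
        for (int a = first[i]; a != -1; a = nxt[a]) {
          int j = to[a];
          if (tree[j] != t) continue;
          if (parent_residual(a, t) > EPS) active.push(j);
          int pj = parent[j];
          if (pj >= 0 && to[pj] == i) { parent[j] = PARENT_ORPHAN; orphans.push(j); }
        }
        tree[i] = FREE;
        parent[i] = PARENT_NONE;
      }
    }
  }

  void run() {
    init();
    while (!active.empty()) {
      int i = active.front(); active.pop();
      uint8_t t = tree[i];
      if (t == FREE) continue;
      bool repush = false;
      for (int a = first[i]; a != -1; a = nxt[a]) {
        double r = (t == TREE_S) ? rcap[a] : rcap[a ^ 1];
        if (r <= EPS) continue;
        int j = to[a];
        if (tree[j] == FREE) {
          tree[j] = t;
          parent[j] = a ^ 1;
          dist[j] = dist[i] + 1;
          ts[j] = ts[i];
          active.push(j);
        } else if (tree[j] != t) {
          int path_arc = (t == TREE_S) ? a : (a ^ 1);
          ++time_now;
          augment(path_arc);
          adopt();
          repush = true;
          break; // adjacency may have changed; revisit this node
        }
      }
      if (repush && tree[i] != FREE) active.push(i);
    }
  }
};

} // namespace

// [[Rcpp::export]]
List bk_mincut_cpp(IntegerVector p, IntegerVector q, NumericVector w,
                   NumericVector cap_src, NumericVector cap_snk) {
  int n = cap_src.size();
  BK bk(n);
  double pre = 0;
  for (int i = 0; i < n; ++i) {
    bk.tr_cap[i] = cap_src[i] - cap_snk[i];
    pre += std::min(cap_src[i], cap_snk[i]);
  }
  for (R_xlen_t e = 0; e < p.size(); ++e)
    if (w[e] > 0) bk.add_edge(p[e] - 1, q[e] - 1, w[e]);
  bk.run();
  IntegerVector lab(n);
  for (int i = 0; i < n; ++i) lab[i] = (bk.tree[i] == TREE_S) ? 1 : 0;
  return List::create(_["flow"] = bk.flow + pre, _["label"] = lab);
}
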