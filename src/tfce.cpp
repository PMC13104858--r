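#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Shared binning: non-strict threshold inclusion (stat >= k*dh), exact floor
// semantics with no floating tolerance.  stat < dh -> bin 0 (no TFCE mass).
static inline int stat_bin(double s, double dh) {
  if (s < dh) return 0;
  return (int)std::floor(s / dh);
}

// nth = ceil(tmax/dh): the top statistic always has a covering threshold.
static inline int n_steps(double tmax, double dh) {
  return (int)std::ceil(tmax / dh);
}

static inline int uf_find(std::vector<int>& p, int x) {
  while (p[x] != x) { p[x] = p[p[x]]; x = p[x]; }
  return x;
}

// ---------------------------------------------------------------------------
// Reference discretized TFCE: recompute connected components from scratch at
// every threshold step with a fresh union-find.  Deliberately shares nothing
// with the incremental engine beyond the bin convention.
// [[Rcpp::export]]
NumericVector cpp_tfce_reference(int n_nodes, IntegerVector u, IntegerVector v,
                                 NumericVector stat, double E, double H, double dh) {
  int ne = u.size();
  NumericVector out(ne);
  double tmax = 0.0;
  for (int e = 0; e < ne; ++e) if (stat[e] > tmax) tmax = stat[e];
  if (tmax <= 0.0) return out;
  int nth = n_steps(tmax, dh);

  std::vector<int> bin(ne);
  for (int e = 0; e < ne; ++e) bin[e] = stat_bin(stat[e], dh);

  std::vector<int> parent(n_nodes), csize(n_nodes), comp_edges(n_nodes);
  for (int k = 1; k <= nth; ++k) {
    double h = k * dh;
    for (int i = 0; i < n_nodes; ++i) { parent[i] = i; csize[i] = 1; }
    for (int e = 0; e < ne; ++e) {
      if (bin[e] < k) continue;
      int a = uf_find(parent, u[e]), b = uf_find(parent, v[e]);
      if (a == b) continue;
      if (csize[a] < csize[b]) std::swap(a, b);
      parent[b] = a;
      csize[a] += csize[b];
    }
    std::fill(comp_edges.begin(), comp_edges.end(), 0);
    for (int e = 0; e < ne; ++e)
      if (bin[e] >= k) comp_edges[uf_find(parent, u[e])]++;
    double w = std::pow(h, H) * dh;
    for (int e = 0; e < ne; ++e)
      if (bin[e] >= k)
        out[e] += std::pow((double)comp_edges[uf_find(parent, u[e])], E) * w;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Incremental-cluster TFCE for FC data.  Clusters are built once from the
// highest bin downward; merges relabel the smaller cluster in full (cluster
// sizes are read for every node at every recorded threshold, so path
// compression alone would not do).  S[k][v] = edge count of v's cluster at
// threshold k*dh; F is accumulated ascending as a streaming row and per-edge
// values are resolved when the row for the edge's bin is complete.
// [[Rcpp::export]]
List cpp_tfce_ic(int n_nodes, IntegerVector u, IntegerVector v,
                 NumericVector stat, double E, double H, double dh,
                 bool keep_state, double max_cells) {
  int ne = u.size();
  NumericVector out(ne);
  double tmax = 0.0;
  for (int e = 0; e < ne; ++e) if (stat[e] > tmax) tmax = stat[e];
  if (tmax <= 0.0)
    return List::create(_["tfce"] = out, _["S"] = R_NilValue, _["F"] = R_NilValue,
                        _["merges"] = 0, _["nth"] = 0, _["tmax"] = tmax);
  int nth = n_steps(tmax, dh);
  if ((double)nth * (double)n_nodes > max_cells)
    stop("accumulator would need %d x %d cells (> max_cells); increase dh, raise the budget, or use the exact engine",
         nth, n_nodes);

  // bucket edges by bin, preserving the (u,v)-lexicographic input order
  std::vector<std::vector<int>> by_bin(nth + 1);
  for (int e = 0; e < ne; ++e) {
    int b = stat_bin(stat[e], dh);
    if (b >= 1) by_bin[b].push_back(e);
  }

  // every node starts as its own empty cluster
  std::vector<int> label(n_nodes), ec(n_nodes, 0);
  std::vector<std::vector<int>> members(n_nodes);
  for (int i = 0; i < n_nodes; ++i) { label[i] = i; members[i].push_back(i); }

  IntegerMatrix S(nth, n_nodes);
  int merges = 0;
  for (int k = nth; k >= 1; --k) {
    for (int e : by_bin[k]) {
      int a = u[e], b = v[e];
      if (a < 0 || a >= n_nodes || b < 0 || b >= n_nodes)
        stop("edge endpoint out of range");
      int la = label[a], lb = label[b];
      if (la == lb) { ec[la]++; continue; }
      if (members[la].size() < members[lb].size()) std::swap(la, lb);
      for (int x : members[lb]) { label[x] = la; members[la].push_back(x); }
      members[lb].clear();
      ec[la] += ec[lb] + 1;
      ec[lb] = 0;
      merges++;
    }
    for (int i = 0; i < n_nodes; ++i) S(k - 1, i) = ec[label[i]];
  }

  NumericMatrix F = keep_state ? NumericMatrix(nth, n_nodes) : NumericMatrix(0, 0);
  std::vector<double> frow(n_nodes, 0.0);
  for (int k = 1; k <= nth; ++k) {
    double w = std::pow(k * dh, H) * dh;
    for (int i = 0; i < n_nodes; ++i) {
      int s = S(k - 1, i);
      if (s > 0) frow[i] += std::pow((double)s, E) * w;
      if (keep_state) F(k - 1, i) = frow[i];
    }
    for (int e : by_bin[k]) out[e] = frow[u[e]];
  }

  return List::create(_["tfce"] = out,
                      _["S"] = keep_state ? (SEXP)S : R_NilValue,
                      _["F"] = keep_state ? (SEXP)F : R_NilValue,
                      _["merges"] = merges, _["nth"] = nth, _["tmax"] = tmax);
}

// ---------------------------------------------------------------------------
// Incremental-cluster TFCE on a voxel graph: nodes activate at their own
// statistic bin (before same-bin edges), edges at the bin of their min-weight;
// cluster size counts NODES and per-node TFCE is accumulated directly after
// each bin, with no accumulation matrix.
// [[Rcpp::export]]
List cpp_tfce_ic_voxel(NumericVector node_stat, IntegerVector u, IntegerVector v,
                       NumericVector w, double E, double H, double dh) {
  int nn = node_stat.size(), ne = u.size();
  NumericVector out(nn);
  double tmax = 0.0;
  for (int i = 0; i < nn; ++i) if (node_stat[i] > tmax) tmax = node_stat[i];
  if (tmax <= 0.0)
    return List::create(_["tfce"] = out, _["merges"] = 0, _["nth"] = 0, _["tmax"] = tmax);
  int nth = n_steps(tmax, dh);

  std::vector<std::vector<int>> node_bin(nth + 1), edge_bin(nth + 1);
  for (int i = 0; i < nn; ++i) {
    int b = stat_bin(node_stat[i], dh);
    if (b >= 1) node_bin[b].push_back(i);
  }
  for (int e = 0; e < ne; ++e) {
    int b = stat_bin(w[e], dh);
    if (b >= 1) edge_bin[b].push_back(e);
  }

  std::vector<int> label(nn, -1), nc(nn, 0);
  std::vector<std::vector<int>> members(nn);
  std::vector<int> active;
  int merges = 0;
  for (int k = nth; k >= 1; --k) {
    for (int i : node_bin[k]) {      // singleton clusters first ...
      label[i] = i;
      nc[i] = 1;
      members[i].assign(1, i);
      active.push_back(i);
    }
    for (int e : edge_bin[k]) {      // ... then same-bin edges
      int la = label[u[e]], lb = label[v[e]];
      if (la < 0 || lb < 0) stop("edge activated before an endpoint voxel");
      if (la == lb) continue;        // no size change for voxel clusters
      if (members[la].size() < members[lb].size()) std::swap(la, lb);
      for (int x : members[lb]) { label[x] = la; members[la].push_back(x); }
      members[lb].clear();
      nc[la] += nc[lb];
      nc[lb] = 0;
      merges++;
    }
    double wgt = std::pow(k * dh, H) * dh;
    for (int i : active) out[i] += std::pow((double)nc[label[i]], E) * wgt;
  }
  return List::create(_["tfce"] = out, _["merges"] = merges,
                      _["nth"] = nth, _["tmax"] = tmax);
}

// ---------------------------------------------------------------------------
// Exact TFCE machinery: running clusters with lazy FlushCluster and parent
// chains.  A merge freezes both constituents (flushed down to the merge
// height) and creates a fresh cluster with score 0, so the value accumulated
// by any entry point is (entry cluster's final score - score at entry) plus
// the full final score of every ancestor.

struct Cluster {
  long size;          // edge count (FC) or node count (voxel)
  double last_h;      // last processed height
  double score;       // size^E * integral(h^H) accumulated since creation
  int parent;         // set when merged away, -1 while live
};

static inline void flush_cluster(std::vector<Cluster>& cls, int c,
                                 double down_to, double E, double H) {
  Cluster& C = cls[c];
  if (down_to < C.last_h) {
    if (C.size > 0)
      C.score += std::pow((double)C.size, E) *
                 (std::pow(C.last_h, H + 1.0) - std::pow(down_to, H + 1.0)) / (H + 1.0);
    C.last_h = down_to;
  }
}

static double chain_value(const std::vector<Cluster>& cls, int entry, double entry_score) {
  double val = cls[entry].score - entry_score;
  int c = cls[entry].parent;
  while (c != -1) { val += cls[c].score; c = cls[c].parent; }
  return val;
}

// Exact TFCE for FC data (cluster size = edge count, one value per edge).
// [[Rcpp::export]]
NumericVector cpp_tfce_exact_fc(int n_nodes, IntegerVector u, IntegerVector v,
                                NumericVector stat, double E, double H) {
  int ne = u.size();
  NumericVector out(ne);
  std::vector<int> ord;
  ord.reserve(ne);
  for (int e = 0; e < ne; ++e) if (stat[e] > 0.0) ord.push_back(e);
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return stat[a] > stat[b]; });

  std::vector<Cluster> cls;
  cls.reserve(2 * n_nodes);
  std::vector<std::vector<int>> members;
  members.reserve(2 * n_nodes);
  std::vector<int> label(n_nodes, -1);
  std::vector<int> entry_cl(ne, -1);
  std::vector<double> entry_score(ne, 0.0);

  auto singleton = [&](int node, double h) {
    if (label[node] >= 0) return;
    cls.push_back({0L, h, 0.0, -1});
    members.push_back(std::vector<int>(1, node));
    label[node] = (int)cls.size() - 1;
  };

  for (int e : ord) {
    double h = stat[e];
    singleton(u[e], h);
    singleton(v[e], h);
    int la = label[u[e]], lb = label[v[e]];
    if (la == lb) {
      flush_cluster(cls, la, h, E, H);
      cls[la].size++;
      entry_cl[e] = la;
      entry_score[e] = cls[la].score;
    } else {
      flush_cluster(cls, la, h, E, H);
      flush_cluster(cls, lb, h, E, H);
      cls.push_back({cls[la].size + cls[lb].size + 1, h, 0.0, -1});
      int c = (int)cls.size() - 1;
      members.push_back(std::vector<int>());
      std::vector<int>& mc = members[c];
      for (int x : members[la]) { label[x] = c; mc.push_back(x); }
      for (int x : members[lb]) { label[x] = c; mc.push_back(x); }
      members[la].clear();
      members[lb].clear();
      cls[la].parent = c;
      cls[lb].parent = c;
      entry_cl[e] = c;
      entry_score[e] = 0.0;
    }
  }
  for (size_t c = 0; c < cls.size(); ++c)
    if (cls[c].parent == -1) flush_cluster(cls, (int)c, 0.0, E, H);
  for (int e = 0; e < ne; ++e)
    if (entry_cl[e] >= 0) out[e] = chain_value(cls, entry_cl[e], entry_score[e]);
  return out;
}

// Exact TFCE on a voxel graph (cluster size = voxel count, one value per
// node).  Node activations and edge activations are interleaved descending by
// height, nodes first at ties.
// [[Rcpp::export]]
NumericVector cpp_tfce_exact_voxel(NumericVector node_stat, IntegerVector u,
                                   IntegerVector v, NumericVector w,
                                   double E, double H) {
  int nn = node_stat.size(), ne = u.size();
  NumericVector out(nn);

  struct Ev { double h; int type; int idx; };   // type 0 = node, 1 = edge
  std::vector<Ev> evs;
  evs.reserve(nn + ne);
  for (int i = 0; i < nn; ++i)
    if (node_stat[i] > 0.0) evs.push_back({node_stat[i], 0, i});
  for (int e = 0; e < ne; ++e)
    if (w[e] > 0.0) evs.push_back({w[e], 1, e});
  std::stable_sort(evs.begin(), evs.end(), [](const Ev& a, const Ev& b) {
    if (a.h != b.h) return a.h > b.h;
    return a.type < b.type;
  });

  std::vector<Cluster> cls;
  cls.reserve(2 * nn);
  std::vector<std::vector<int>> members;
  members.reserve(2 * nn);
  std::vector<int> label(nn, -1), entry_cl(nn, -1);

  for (const Ev& ev : evs) {
    if (ev.type == 0) {
      int i = ev.idx;
      cls.push_back({1L, ev.h, 0.0, -1});
      members.push_back(std::vector<int>(1, i));
      label[i] = (int)cls.size() - 1;
      entry_cl[i] = label[i];
    } else {
      int e = ev.idx;
      int la = label[u[e]], lb = label[v[e]];
      if (la < 0 || lb < 0) stop("edge activated before an endpoint voxel");
      if (la == lb) continue;
      flush_cluster(cls, la, ev.h, E, H);
      flush_cluster(cls, lb, ev.h, E, H);
      cls.push_back({cls[la].size + cls[lb].size, ev.h, 0.0, -1});
      int c = (int)cls.size() - 1;
      members.push_back(std::vector<int>());
      std::vector<int>& mc = members[c];
      for (int x : members[la]) { label[x] = c; mc.push_back(x); }
      for (int x : members[lb]) { label[x] = c; mc.push_back(x); }
      members[la].clear();
      members[lb].clear();
      cls[la].parent = c;
      cls[lb].parent = c;
    }
  }
  for (size_t c = 0; c < cls.size(); ++c)
    if (cls[c].parent == -1) flush_cluster(cls, (int)c, 0.0, E, H);
  for (int i = 0; i < nn; ++i)
    if (entry_cl[i] >= 0) out[i] = chain_value(cls, entry_cl[i], 0.0);
  return out;
}
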