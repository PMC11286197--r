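#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Shared kernels for the activity-driven network generator and the
// agent-based evolutionary game simulator.  All functions use R's RNG
// (via unif_rand), so set.seed() at the R level makes every result
// reproducible.  Node ids are 1-based on the R side; internally 0-based.

typedef long long ekey;

// Append one instantaneous activity-driven snapshot to `keys`.
// Each node u is active w.p. a[u]; an active node draws m distinct
// partners uniformly from V \ {u} (draw-by-draw rejection, which yields a
// uniform sample without replacement).  Edges are stored as sorted-pair
// keys; union semantics (dedup) is applied by the caller.
static void snapshot_keys(const NumericVector& a, int m, std::vector<ekey>& keys) {
  const int N = a.size();
  std::vector<int> drawn(m);
  for (int u = 0; u < N; ++u) {
    if (unif_rand() >= a[u]) continue;
    int got = 0;
    while (got < m) {
      int v = (int)(unif_rand() * N);
      if (v >= N) v = N - 1;   // guard against unif_rand() == 1.0
      if (v == u) continue;
      bool dup = false;
      for (int j = 0; j < got; ++j) if (drawn[j] == v) { dup = true; break; }
      if (dup) continue;
      drawn[got++] = v;
      int lo = u < v ? u : v, hi = u < v ? v : u;
      keys.push_back((ekey)lo * N + hi);
    }
  }
}

static void dedup(std::vector<ekey>& keys) {
  std::sort(keys.begin(), keys.end());
  keys.erase(std::unique(keys.begin(), keys.end()), keys.end());
}

static IntegerMatrix keys_to_edges(const std::vector<ekey>& keys, int N) {
  const int E = keys.size();
  IntegerMatrix out(E, 2);
  for (int e = 0; e < E; ++e) {
    out(e, 0) = (int)(keys[e] / N) + 1;
    out(e, 1) = (int)(keys[e] % N) + 1;
  }
  return out;
}

// One instantaneous graph G(tau), as a 2-column (u < v, 1-based) edge matrix.
// [[Rcpp::export]]
IntegerMatrix cpp_snapshot_edges(NumericVector a, int m) {
  std::vector<ekey> keys;
  snapshot_keys(a, m, keys);
  dedup(keys);
  return keys_to_edges(keys, a.size());
}

// Integrated graph G_delta: union of delta fresh snapshots.
// If multigraph, keep per-edge snapshot multiplicities in column 3.
// [[Rcpp::export]]
IntegerMatrix cpp_window_edges(NumericVector a, int m, int delta, bool multigraph) {
  const int N = a.size();
  std::vector<ekey> keys;
  for (int d = 0; d < delta; ++d) {
    std::vector<ekey> snap;
    snapshot_keys(a, m, snap);
    dedup(snap);  // a snapshot is itself simple
    keys.insert(keys.end(), snap.begin(), snap.end());
  }
  std::sort(keys.begin(), keys.end());
  if (!multigraph) {
    keys.erase(std::unique(keys.begin(), keys.end()), keys.end());
    return keys_to_edges(keys, N);
  }
  // run-length encode multiplicities
  std::vector<ekey> uk; std::vector<int> mult;
  for (size_t i = 0; i < keys.size(); ) {
    size_t j = i;
    while (j < keys.size() && keys[j] == keys[i]) ++j;
    uk.push_back(keys[i]); mult.push_back((int)(j - i));
    i = j;
  }
  IntegerMatrix out(uk.size(), 3);
  for (size_t e = 0; e < uk.size(); ++e) {
    out(e, 0) = (int)(uk[e] / N) + 1;
    out(e, 1) = (int)(uk[e] % N) + 1;
    out(e, 2) = mult[e];
  }
  return out;
}

// Accumulated payoffs: P_u = sum over neighbours v of A(s_u, s_v).
// s is 1-based strategy index; isolated nodes get 0.
// [[Rcpp::export]]
NumericVector cpp_accumulate_payoffs(IntegerMatrix edges, IntegerVector s,
                                     NumericMatrix A, int N) {
  NumericVector P(N);
  const int E = edges.nrow();
  for (int e = 0; e < E; ++e) {
    int u = edges(e, 0) - 1, v = edges(e, 1) - 1;
    P[u] += A(s[u] - 1, s[v] - 1);
    P[v] += A(s[v] - 1, s[u] - 1);
  }
  return P;
}

static inline double fermi(double beta_dP) {
  if (beta_dP > 40.0) return 1.0;
  if (beta_dP < -40.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-beta_dP));
}

// Build CSR adjacency into (deg, off, adj); adj holds 0-based neighbours.
static void build_adj(const IntegerMatrix& edges, int N,
                      std::vector<int>& deg, std::vector<int>& off,
                      std::vector<int>& adj) {
  const int E = edges.nrow();
  deg.assign(N, 0);
  for (int e = 0; e < E; ++e) {
    ++deg[edges(e, 0) - 1];
    ++deg[edges(e, 1) - 1];
  }
  off.assign(N + 1, 0);
  for (int u = 0; u < N; ++u) off[u + 1] = off[u] + deg[u];
  adj.assign(2 * E, 0);
  std::vector<int> fill(off.begin(), off.end() - 1);
  for (int e = 0; e < E; ++e) {
    int u = edges(e, 0) - 1, v = edges(e, 1) - 1;
    adj[fill[u]++] = v;
    adj[fill[v]++] = u;
  }
}

// Fermi imitation step.  synchronous: all nodes decide from the pre-update
// state; otherwise nodes are visited in a random order and read the current
// (partially updated) strategies, with payoffs frozen from the game phase.
// [[Rcpp::export]]
IntegerVector cpp_update_strategies(IntegerMatrix edges, IntegerVector s,
                                    NumericVector P, double beta,
                                    bool synchronous) {
  const int N = s.size();
  std::vector<int> deg, off, adj;
  build_adj(edges, N, deg, off, adj);
  IntegerVector s_new = clone(s);
  if (synchronous) {
    for (int u = 0; u < N; ++u) {
      if (deg[u] == 0) continue;
      int k = (int)(unif_rand() * deg[u]);
      if (k >= deg[u]) k = deg[u] - 1;
      int v = adj[off[u] + k];
      if (unif_rand() < fermi(beta * (P[v] - P[u]))) s_new[u] = s[v];
    }
  } else {
    std::vector<int> order(N);
    for (int u = 0; u < N; ++u) order[u] = u;
    for (int i = N - 1; i > 0; --i) {    // Fisher-Yates with R RNG
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }
    for (int i = 0; i < N; ++i) {
      int u = order[i];
      if (deg[u] == 0) continue;
      int k = (int)(unif_rand() * deg[u]);
      if (k >= deg[u]) k = deg[u] - 1;
      int v = adj[off[u] + k];
      if (unif_rand() < fermi(beta * (P[v] - P[u]))) s_new[u] = s_new[v];
    }
  }
  return s_new;
}

// Full ABM loop: per step build G_delta, accumulate payoffs, update, and
// (from step record_from on) record I^k_si = (1/N) sum_{u: s_u=i} a_u^k for
// k = 0..kmax.  Returns the recorded moment series (rows: recorded steps;
// cols: strategy-major, i.e. (i-1)*(kmax+1) + k + 1) and the full frequency
// trajectory (steps x n).
//
// The union graph is built without a global edge sort: raw directed stubs
// from all delta snapshots are bucketed into per-node adjacency slices,
// and each short slice is sorted/uniqued locally (an edge drawn twice in a
// window is removed from both endpoints' slices).  All buffers persist
// across steps.
// [[Rcpp::export]]
List cpp_run_abm(NumericVector a, IntegerVector s0, NumericMatrix A,
                 double beta, int m, int delta, int steps, int kmax,
                 int record_from, bool synchronous) {
  const int N = a.size();
  const int n = A.nrow();
  IntegerVector s = clone(s0);
  // precompute a^k
  std::vector<double> apow((size_t)N * (kmax + 1));
  for (int u = 0; u < N; ++u) {
    double p = 1.0;
    for (int k = 0; k <= kmax; ++k) { apow[(size_t)u * (kmax + 1) + k] = p; p *= a[u]; }
  }
  const int nrec = steps - record_from + 1 > 0 ? steps - record_from + 1 : 0;
  NumericMatrix rec(nrec, n * (kmax + 1));
  NumericMatrix freq(steps, n);
  std::vector<int> su, sv;            // raw stub endpoints (one per edge)
  su.reserve((size_t)N * m); sv.reserve((size_t)N * m);
  std::vector<int> deg(N), off(N + 1), fill(N), adj;
  std::vector<int> drawn(m), s_old(N);
  std::vector<double> P(N);
  std::vector<double> I((size_t)n * (kmax + 1));
  std::vector<int> order;
  int ri = 0;
  for (int t = 1; t <= steps; ++t) {
    // game phase: delta activity-driven snapshots, union semantics
    su.clear(); sv.clear();
    for (int d = 0; d < delta; ++d) {
      for (int u = 0; u < N; ++u) {
        if (unif_rand() >= a[u]) continue;
        int got = 0;
        while (got < m) {
          int v = (int)(unif_rand() * N);
          if (v >= N) v = N - 1;
          if (v == u) continue;
          bool dup = false;
          for (int j = 0; j < got; ++j) if (drawn[j] == v) { dup = true; break; }
          if (dup) continue;
          drawn[got++] = v;
          su.push_back(u); sv.push_back(v);
        }
      }
    }
    const int E = su.size();
    // bucket stubs into per-node slices
    std::fill(deg.begin(), deg.end(), 0);
    for (int e = 0; e < E; ++e) { ++deg[su[e]]; ++deg[sv[e]]; }
    off[0] = 0;
    for (int u = 0; u < N; ++u) off[u + 1] = off[u] + deg[u];
    adj.resize(2 * (size_t)E);
    std::copy(off.begin(), off.end() - 1, fill.begin());
    for (int e = 0; e < E; ++e) {
      adj[fill[su[e]]++] = sv[e];
      adj[fill[sv[e]]++] = su[e];
    }
    // local dedup (collapses multi-edges consistently at both endpoints)
    // and accumulated payoffs in the same pass
    std::fill(P.begin(), P.end(), 0.0);
    for (int u = 0; u < N; ++u) {
      if (deg[u] == 0) continue;
      int* b = &adj[off[u]];
      std::sort(b, b + deg[u]);
      int d2 = (int)(std::unique(b, b + deg[u]) - b);
      deg[u] = d2;
      const int row = s[u] - 1;
      double pu = 0.0;
      for (int j = 0; j < d2; ++j) pu += A(row, s[b[j]] - 1);
      P[u] = pu;
    }
    // strategy updating phase
    if (synchronous) {
      std::copy(s.begin(), s.end(), s_old.begin());
      for (int u = 0; u < N; ++u) {
        if (deg[u] == 0) continue;
        int k = (int)(unif_rand() * deg[u]);
        if (k >= deg[u]) k = deg[u] - 1;
        int v = adj[off[u] + k];
        if (unif_rand() < fermi(beta * (P[v] - P[u]))) s[u] = s_old[v];
      }
    } else {
      order.resize(N);
      for (int u = 0; u < N; ++u) order[u] = u;
      for (int i = N - 1; i > 0; --i) {
        int j = (int)(unif_rand() * (i + 1));
        if (j > i) j = i;
        std::swap(order[i], order[j]);
      }
      for (int i = 0; i < N; ++i) {
        int u = order[i];
        if (deg[u] == 0) continue;
        int k = (int)(unif_rand() * deg[u]);
        if (k >= deg[u]) k = deg[u] - 1;
        int v = adj[off[u] + k];
        if (unif_rand() < fermi(beta * (P[v] - P[u]))) s[u] = s[v];
      }
    }
    // observables: frequencies every step, full moment table when recording
    if (t >= record_from) {
      std::fill(I.begin(), I.end(), 0.0);
      for (int u = 0; u < N; ++u) {
        const double* ap = &apow[(size_t)u * (kmax + 1)];
        double* Ii = &I[(size_t)(s[u] - 1) * (kmax + 1)];
        for (int k = 0; k <= kmax; ++k) Ii[k] += ap[k];
      }
      for (int i = 0; i < n; ++i) {
        freq(t - 1, i) = I[(size_t)i * (kmax + 1)] / N;
        for (int k = 0; k <= kmax; ++k)
          rec(ri, i * (kmax + 1) + k) = I[(size_t)i * (kmax + 1) + k] / N;
      }
      ++ri;
    } else {
      std::vector<int> cnt(n, 0);
      for (int u = 0; u < N; ++u) ++cnt[s[u] - 1];
      for (int i = 0; i < n; ++i) freq(t - 1, i) = (double)cnt[i] / N;
    }
    if (t % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["moments"] = rec, _["freq"] = freq,
                      _["final_strategies"] = s);
}
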