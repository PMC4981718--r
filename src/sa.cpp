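#include <Rcpp.h>
#include <unordered_set>
#include <vector>
using namespace Rcpp;

// Barber bipartite modularity machinery shared by the annealer and the
// greedy polish. Nodes 0..ng-1 are genomes, ng..ng+nf-1 are families.
// Q = e_in / L - sum_m Kg[m] * Kf[m] / L^2, where e_in counts edges whose
// endpoints share a module and Kg/Kf are summed degrees per module per class.

struct SAState {
  int ng, nf, n;
  long L;
  std::vector<std::vector<int>> adj;   // neighbor lists
  std::vector<int> deg;
  std::vector<int> label;
  std::vector<double> Kg, Kf;
  std::vector<int> msize;              // nodes per module
  std::vector<int> free_ids;
  double e_in, sum_prod;

  void init(const IntegerVector& eg, const IntegerVector& ef, int ng_, int nf_) {
    ng = ng_; nf = nf_; n = ng + nf; L = eg.size();
    adj.assign(n, {});
    for (long e = 0; e < L; ++e) {
      int g = eg[e], f = ef[e] + ng;
      adj[g].push_back(f);
      adj[f].push_back(g);
    }
    deg.assign(n, 0);
    for (int v = 0; v < n; ++v) deg[v] = (int)adj[v].size();
    label.resize(n);
    for (int v = 0; v < n; ++v) label[v] = v;   // singleton start
    Kg.assign(n, 0.0); Kf.assign(n, 0.0);
    msize.assign(n, 1);
    for (int v = 0; v < ng; ++v) Kg[v] = deg[v];
    for (int v = ng; v < n; ++v) Kf[v] = deg[v];
    e_in = 0.0;
    sum_prod = 0.0;                              // singletons: Kg*Kf = 0 everywhere
    free_ids.clear();
  }

  void set_labels(const std::vector<int>& lab) {
    label = lab;
    Kg.assign(n, 0.0); Kf.assign(n, 0.0); msize.assign(n, 0);
    for (int v = 0; v < n; ++v) {
      msize[label[v]]++;
      if (v < ng) Kg[label[v]] += deg[v]; else Kf[label[v]] += deg[v];
    }
    free_ids.clear();
    for (int m = 0; m < n; ++m) if (msize[m] == 0) free_ids.push_back(m);
    sum_prod = 0.0;
    for (int m = 0; m < n; ++m) sum_prod += Kg[m] * Kf[m];
    e_in = 0.0;
    for (int v = 0; v < ng; ++v)
      for (int u : adj[v]) if (label[u] == label[v]) e_in += 1.0;
  }

  double q() const {
    return e_in / (double)L - sum_prod / ((double)L * (double)L);
  }

  // ΔQ of moving node v to module b (counts neighbors in current and target)
  double delta_move(int v, int b, int* cnt_a_out, int* cnt_b_out) const {
    int a = label[v];
    int ca = 0, cb = 0;
    for (int u : adj[v]) {
      if (label[u] == a) ++ca;
      else if (label[u] == b) ++cb;
    }
    double dsum;
    if (v < ng) dsum = (double)deg[v] * (Kf[b] - Kf[a]);
    else        dsum = (double)deg[v] * (Kg[b] - Kg[a]);
    *cnt_a_out = ca; *cnt_b_out = cb;
    return (cb - ca) / (double)L - dsum / ((double)L * (double)L);
  }

  void apply_move(int v, int b, int ca, int cb) {
    int a = label[v];
    if (v < ng) { sum_prod += (double)deg[v] * (Kf[b] - Kf[a]);
                  Kg[a] -= deg[v]; Kg[b] += deg[v]; }
    else        { sum_prod += (double)deg[v] * (Kg[b] - Kg[a]);
                  Kf[a] -= deg[v]; Kf[b] += deg[v]; }
    e_in += cb - ca;
    label[v] = b;
    msize[a]--; msize[b]++;
    if (msize[a] == 0) free_ids.push_back(a);
  }
};

static int cross_edges(const SAState& st, const IntegerVector& eg,
                       const IntegerVector& ef, int a, int b) {
  int cnt = 0;
  for (long e = 0; e < st.L; ++e) {
    int lg = st.label[eg[e]], lf = st.label[ef[e] + st.ng];
    if ((lg == a && lf == b) || (lg == b && lf == a)) ++cnt;
  }
  return cnt;
}

// Greedy single-node polish: move every node to its best neighboring (or
// fresh) module until no improving move remains. Guarantees a local maximum
// under the single-node move set.
static void greedy_polish(SAState& st) {
  const double eps = 1e-12;
  bool improved = true;
  int pass = 0;
  while (improved && pass < 200) {
    improved = false; ++pass;
    for (int v = 0; v < st.n; ++v) {
      int a = st.label[v];
      // candidate modules: those of neighbors, plus a fresh singleton
      double best_dq = eps; int best_b = -1, best_ca = 0, best_cb = 0;
      for (size_t i = 0; i < st.adj[v].size(); ++i) {
        int b = st.label[st.adj[v][i]];
        if (b == a) continue;
        int ca, cb;
        double dq = st.delta_move(v, b, &ca, &cb);
        if (dq > best_dq) { best_dq = dq; best_b = b; best_ca = ca; best_cb = cb; }
      }
      if (st.msize[a] > 1 && !st.free_ids.empty()) {
        int b = st.free_ids.back();
        int ca, cb;
        double dq = st.delta_move(v, b, &ca, &cb);
        if (dq > best_dq) { best_dq = dq; best_b = b; best_ca = ca; best_cb = cb; }
      }
      if (best_b >= 0) {
        if (st.msize[best_b] == 0 && !st.free_ids.empty() &&
            st.free_ids.back() == best_b)
          st.free_ids.pop_back();
        st.apply_move(v, best_b, best_ca, best_cb);
        improved = true;
      }
    }
  }
}

// [[Rcpp::export]]
List cpp_sa_partition(IntegerVector eg, IntegerVector ef, int ng, int nf,
                      double t0, double cooling, double fresh_prob,
                      double sweep_factor, double patience_factor,
                      int max_sweeps) {
  if (eg.size() != ef.size()) stop("edge vectors differ in length");
  if (eg.size() == 0) stop("empty network");
  SAState st;
  st.init(eg, ef, ng, nf);
  const int n = st.n;
  const double Ld = (double)st.L;

  // temperature calibration: typical proposal magnitude, accept ~50% uphill
  if (t0 <= 0) {
    double acc = 0; int cnt = 0;
    for (int i = 0; i < 200; ++i) {
      int v = (int)(unif_rand() * n); if (v >= n) v = n - 1;
      if (st.adj[v].empty()) continue;
      int u = st.adj[v][(int)(unif_rand() * st.adj[v].size())];
      int b = st.label[u];
      if (b == st.label[v]) continue;
      int ca, cb;
      double dq = st.delta_move(v, b, &ca, &cb);
      acc += std::fabs(dq); ++cnt;
    }
    t0 = (cnt > 0 ? acc / cnt : 1.0 / Ld) / 0.6931472;
    if (t0 <= 0) t0 = 1.0 / Ld;
  }

  double T = t0;
  std::vector<int> best = st.label;
  double bestQ = st.q();
  long moves_since_best = 0;
  const long patience_moves = (long)(patience_factor * n) + 1;
  const int moves_per_sweep = std::max(1, (int)(sweep_factor * n));

  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    for (int mv = 0; mv < moves_per_sweep; ++mv) {
      int v = (int)(unif_rand() * n); if (v >= n) v = n - 1;
      if (st.adj[v].empty()) continue;
      int b;
      if (!st.free_ids.empty() && st.msize[st.label[v]] > 1 &&
          unif_rand() < fresh_prob) {
        b = st.free_ids.back();
      } else {
        int u = st.adj[v][(int)(unif_rand() * st.adj[v].size())];
        b = st.label[u];
      }
      if (b == st.label[v]) { ++moves_since_best; continue; }
      int ca, cb;
      double dq = st.delta_move(v, b, &ca, &cb);
      if (dq >= 0 || unif_rand() < std::exp(dq / T)) {
        if (st.msize[b] == 0 && !st.free_ids.empty() && st.free_ids.back() == b)
          st.free_ids.pop_back();
        st.apply_move(v, b, ca, cb);
        double q = st.q();
        if (q > bestQ + 1e-12) { bestQ = q; best = st.label; moves_since_best = 0; }
        else ++moves_since_best;
      } else ++moves_since_best;
    }
    // occasional module-merge proposal
    {
      int v = (int)(unif_rand() * n), u = (int)(unif_rand() * n);
      if (v < n && u < n) {
        int a = st.label[v], b = st.label[u];
        if (a != b) {
          int cnt = cross_edges(st, eg, ef, a, b);
          double dsum = st.Kg[a] * st.Kf[b] + st.Kg[b] * st.Kf[a];
          double dq = cnt / Ld - dsum / (Ld * Ld);
          if (dq >= 0 || unif_rand() < std::exp(dq / T)) {
            for (int w = 0; w < n; ++w) if (st.label[w] == b) {
              st.label[w] = a;
              st.msize[b]--; st.msize[a]++;
            }
            st.sum_prod += dsum;
            st.Kg[a] += st.Kg[b]; st.Kf[a] += st.Kf[b];
            st.Kg[b] = 0; st.Kf[b] = 0;
            st.e_in += cnt;
            st.free_ids.push_back(b);
            double q = st.q();
            if (q > bestQ + 1e-12) { bestQ = q; best = st.label; moves_since_best = 0; }
          }
        }
      }
    }
    T *= cooling;
    if (moves_since_best > patience_moves && T < t0 * 1e-4) break;
  }

  st.set_labels(best);
  greedy_polish(st);
  // consolidate: move singleton-module nodes to a neighbor module when the
  // move is exactly Q-neutral (e.g. an isolated edge joins into one module)
  for (int v = 0; v < st.n; ++v) {
    if (st.msize[st.label[v]] != 1 || st.adj[v].empty()) continue;
    for (size_t i = 0; i < st.adj[v].size(); ++i) {
      int b = st.label[st.adj[v][i]];
      if (b == st.label[v]) continue;
      int ca, cb;
      double dq = st.delta_move(v, b, &ca, &cb);
      if (dq > -1e-12) { st.apply_move(v, b, ca, cb); break; }
    }
  }

  return List::create(_["labels"] = IntegerVector(st.label.begin(), st.label.end()),
                      _["q"] = st.q());
}

// Degree-preserving randomization of a bipartite edge list by double-edge
// swaps: (g1,f1),(g2,f2) -> (g1,f2),(g2,f1), rejecting swaps that would
// duplicate an existing edge. Every node keeps its degree exactly.
// [[Rcpp::export]]
List cpp_edge_swap(IntegerVector eg, IntegerVector ef, int ng, int nf,
                   int n_swaps) {
  long L = eg.size();
  if (L < 2) stop("network too small to swap");
  std::vector<int> g(eg.begin(), eg.end()), f(ef.begin(), ef.end());
  std::unordered_set<long long> edges;
  edges.reserve(L * 2);
  for (long e = 0; e < L; ++e) edges.insert((long long)g[e] * nf + f[e]);
  long done = 0;
  for (long a = 0; a < (long)n_swaps; ++a) {
    long e1 = (long)(unif_rand() * L), e2 = (long)(unif_rand() * L);
    if (e1 >= L) e1 = L - 1; if (e2 >= L) e2 = L - 1;
    if (e1 == e2) continue;
    int g1 = g[e1], f1 = f[e1], g2 = g[e2], f2 = f[e2];
    if (g1 == g2 || f1 == f2) continue;
    long long k1 = (long long)g1 * nf + f2, k2 = (long long)g2 * nf + f1;
    if (edges.count(k1) || edges.count(k2)) continue;
    edges.erase((long long)g1 * nf + f1);
    edges.erase((long long)g2 * nf + f2);
    edges.insert(k1); edges.insert(k2);
    f[e1] = f2; f[e2] = f1;
    ++done;
  }
  return List::create(_["eg"] = IntegerVector(g.begin(), g.end()),
                      _["ef"] = IntegerVector(f.begin(), f.end()),
                      _["n_swapped"] = (double)done);
}
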