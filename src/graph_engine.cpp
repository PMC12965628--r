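// Binary-graph metric engine: BFS distances, Brandes betweenness,
// clustering, local efficiency, Maslov-Sneppen rewiring, Louvain modularity.
// Graphs are undirected, simple, binary; adjacency passed as 0/1 integer
// matrices with zero diagonal. All randomness uses an explicit mt19937_64
// seed so results are reproducible independent of R's RNG state.
#include <Rcpp.h>
#include <random>
#include <vector>
#include <queue>
#include <stack>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

static std::vector<std::vector<int>> adj_list(const IntegerMatrix &A) {
  int n = A.nrow();
  std::vector<std::vector<int>> nb(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (A(i, j) != 0 && i != j) nb[i].push_back(j);
  return nb;
}

// [[Rcpp::export(name = ".cpp_bfs_distances")]]
NumericMatrix cpp_bfs_distances(const IntegerMatrix &A) {
  int n = A.nrow();
  std::vector<std::vector<int>> nb = adj_list(A);
  NumericMatrix D(n, n);
  std::fill(D.begin(), D.end(), R_PosInf);
  std::vector<int> dist(n);
  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    dist[s] = 0;
    std::queue<int> q;
    q.push(s);
    while (!q.empty()) {
      int v = q.front(); q.pop();
      for (int w : nb[v]) if (dist[w] < 0) { dist[w] = dist[v] + 1; q.push(w); }
    }
    for (int t = 0; t < n; ++t) if (dist[t] >= 0) D(s, t) = dist[t];
  }
  return D;
}

// Brandes (2001) accumulation; returns raw (unnormalised) betweenness for
// undirected graphs (each pair counted once).
// [[Rcpp::export(name = ".cpp_betweenness")]]
NumericVector cpp_betweenness(const IntegerMatrix &A) {
  int n = A.nrow();
  std::vector<std::vector<int>> nb = adj_list(A);
  NumericVector bc(n, 0.0);
  std::vector<double> sigma(n), delta(n);
  std::vector<int> dist(n);
  std::vector<std::vector<int>> pred(n);
  for (int s = 0; s < n; ++s) {
    std::stack<int> S;
    for (int i = 0; i < n; ++i) pred[i].clear();
    std::fill(sigma.begin(), sigma.end(), 0.0);
    std::fill(dist.begin(), dist.end(), -1);
    sigma[s] = 1.0; dist[s] = 0;
    std::queue<int> Q;
    Q.push(s);
    while (!Q.empty()) {
      int v = Q.front(); Q.pop();
      S.push(v);
      for (int w : nb[v]) {
        if (dist[w] < 0) { dist[w] = dist[v] + 1; Q.push(w); }
        if (dist[w] == dist[v] + 1) { sigma[w] += sigma[v]; pred[w].push_back(v); }
      }
    }
    std::fill(delta.begin(), delta.end(), 0.0);
    while (!S.empty()) {
      int w = S.top(); S.pop();
      for (int v : pred[w]) delta[v] += sigma[v] / sigma[w] * (1.0 + delta[w]);
      if (w != s) bc[w] += delta[w];
    }
  }
  // each unordered pair was accumulated from both endpoints
  for (int i = 0; i < n; ++i) bc[i] /= 2.0;
  return bc;
}

// [[Rcpp::export(name = ".cpp_clustering")]]
NumericVector cpp_clustering(const IntegerMatrix &A) {
  int n = A.nrow();
  std::vector<std::vector<int>> nb = adj_list(A);
  NumericVector cc(n, 0.0);
  for (int i = 0; i < n; ++i) {
    int k = (int) nb[i].size();
    if (k < 2) continue;
    int links = 0;
    for (int a = 0; a < k; ++a)
      for (int b = a + 1; b < k; ++b)
        if (A(nb[i][a], nb[i][b]) != 0) ++links;
    cc[i] = 2.0 * links / (double(k) * (k - 1));
  }
  return cc;
}

static double subgraph_global_efficiency(const IntegerMatrix &A,
                                         const std::vector<int> &nodes) {
  int m = (int) nodes.size();
  if (m < 2) return 0.0;
  // BFS within the induced subgraph
  double acc = 0.0;
  std::vector<int> dist(m);
  std::vector<std::vector<int>> nb(m);
  for (int a = 0; a < m; ++a)
    for (int b = 0; b < m; ++b)
      if (a != b && A(nodes[a], nodes[b]) != 0) nb[a].push_back(b);
  for (int s = 0; s < m; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    dist[s] = 0;
    std::queue<int> q; q.push(s);
    while (!q.empty()) {
      int v = q.front(); q.pop();
      for (int w : nb[v]) if (dist[w] < 0) { dist[w] = dist[v] + 1; q.push(w); }
    }
    for (int t = 0; t < m; ++t)
      if (t != s && dist[t] > 0) acc += 1.0 / dist[t];
  }
  return acc / (double(m) * (m - 1));
}

// [[Rcpp::export(name = ".cpp_local_efficiency")]]
NumericVector cpp_local_efficiency(const IntegerMatrix &A) {
  int n = A.nrow();
  std::vector<std::vector<int>> nb = adj_list(A);
  NumericVector le(n, 0.0);
  for (int i = 0; i < n; ++i) {
    if ((int) nb[i].size() < 2) continue;
    le[i] = subgraph_global_efficiency(A, nb[i]);
  }
  return le;
}

// Maslov-Sneppen double-edge-swap core shared by the single-graph export
// and the batched small-world reference generator, so both produce
// identical rewirings for identical seeds.
static void double_edge_swap_core(std::vector<std::pair<int, int>> &el,
                                  std::vector<std::vector<char>> &adj,
                                  int n_swaps, std::mt19937_64 &rng) {
  int m = (int) el.size();
  if (m < 2) return;
  std::uniform_int_distribution<int> pick(0, m - 1);
  std::uniform_int_distribution<int> coin(0, 1);
  for (int s = 0; s < n_swaps; ++s) {
    int e1 = pick(rng), e2 = pick(rng);
    if (e1 == e2) continue;
    int a = el[e1].first, b = el[e1].second;
    int c = el[e2].first, d = el[e2].second;
    if (coin(rng)) std::swap(c, d);
    // proposed: (a,d) and (c,b)
    if (a == d || c == b) continue;
    if (adj[a][d] || adj[c][b]) continue;
    adj[a][b] = adj[b][a] = 0;
    adj[c][d] = adj[d][c] = 0;
    adj[a][d] = adj[d][a] = 1;
    adj[c][b] = adj[b][c] = 1;
    el[e1] = {a, d};
    el[e2] = {c, b};
  }
}

static void edges_to_state(const IntegerMatrix &edges, int n_nodes,
                           std::vector<std::pair<int, int>> &el,
                           std::vector<std::vector<char>> &adj) {
  int m = edges.nrow();
  el.assign(m, {0, 0});
  adj.assign(n_nodes, std::vector<char>(n_nodes, 0));
  for (int e = 0; e < m; ++e) {
    int u = edges(e, 0), v = edges(e, 1);
    el[e] = {u, v};
    adj[u][v] = adj[v][u] = 1;
  }
}

// Maslov-Sneppen degree-preserving rewiring by double edge swaps.
// edges: m x 2 (0-based). Attempts n_swaps swaps; a swap is rejected when it
// would create a self-loop or multi-edge. Returns rewired edge list.
// [[Rcpp::export(name = ".cpp_double_edge_swap")]]
IntegerMatrix cpp_double_edge_swap(const IntegerMatrix &edges, int n_nodes,
                                   int n_swaps, double seed) {
  std::vector<std::pair<int, int>> el;
  std::vector<std::vector<char>> adj;
  edges_to_state(edges, n_nodes, el, adj);
  std::mt19937_64 rng((uint64_t) seed);
  double_edge_swap_core(el, adj, n_swaps, rng);
  int m = (int) el.size();
  IntegerMatrix out(m, 2);
  for (int e = 0; e < m; ++e) {
    out(e, 0) = std::min(el[e].first, el[e].second);
    out(e, 1) = std::max(el[e].first, el[e].second);
  }
  return out;
}

// mean clustering coefficient and reachable-pairs mean path length of the
// graph held in (el, adj) form
static void cp_lp_of_state(const std::vector<std::pair<int, int>> &el,
                           const std::vector<std::vector<char>> &adj,
                           int n_nodes, double &cp, double &lp) {
  std::vector<std::vector<int>> nb(n_nodes);
  for (auto &e : el) { nb[e.first].push_back(e.second);
                       nb[e.second].push_back(e.first); }
  double cc_sum = 0.0;
  for (int i = 0; i < n_nodes; ++i) {
    int k = (int) nb[i].size();
    if (k < 2) continue;
    int links = 0;
    for (int a = 0; a < k; ++a)
      for (int b = a + 1; b < k; ++b)
        if (adj[nb[i][a]][nb[i][b]]) ++links;
    cc_sum += 2.0 * links / (double(k) * (k - 1));
  }
  cp = cc_sum / n_nodes;
  double dsum = 0.0;
  long npairs = 0;
  std::vector<int> dist(n_nodes);
  for (int s = 0; s < n_nodes; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    dist[s] = 0;
    std::queue<int> q; q.push(s);
    while (!q.empty()) {
      int v = q.front(); q.pop();
      for (int w : nb[v]) if (dist[w] < 0) { dist[w] = dist[v] + 1; q.push(w); }
    }
    for (int t = 0; t < n_nodes; ++t)
      if (t != s && dist[t] > 0) { dsum += dist[t]; ++npairs; }
  }
  lp = npairs ? dsum / npairs : R_NaReal;
}

// Batched small-world references: for each seed, rewire a copy of the input
// edge list (same procedure as .cpp_double_edge_swap) and return the
// reference's mean clustering coefficient and reachable-pairs
// characteristic path length. Rows align with `seeds`.
// [[Rcpp::export(name = ".cpp_sw_refs")]]
NumericMatrix cpp_sw_refs(const IntegerMatrix &edges, int n_nodes,
                          int n_swaps, const NumericVector &seeds) {
  int m_refs = seeds.size();
  NumericMatrix out(m_refs, 2);
  std::vector<std::pair<int, int>> el0, el;
  std::vector<std::vector<char>> adj0, adj;
  edges_to_state(edges, n_nodes, el0, adj0);
  for (int r = 0; r < m_refs; ++r) {
    el = el0; adj = adj0;
    std::mt19937_64 rng((uint64_t) seeds[r]);
    double_edge_swap_core(el, adj, n_swaps, rng);
    double cp, lp;
    cp_lp_of_state(el, adj, n_nodes, cp, lp);
    out(r, 0) = cp;
    out(r, 1) = lp;
  }
  return out;
}

// Newman modularity of a given membership
static double modularity_of(const std::vector<std::vector<int>> &nb,
                            const std::vector<double> &deg, double two_m,
                            const std::vector<int> &memb) {
  double q = 0.0;
  int n = (int) nb.size();
  std::vector<double> sum_in(n, 0.0), sum_tot(n, 0.0);
  for (int i = 0; i < n; ++i) {
    sum_tot[memb[i]] += deg[i];
    for (int j : nb[i]) if (memb[j] == memb[i]) sum_in[memb[i]] += 1.0;
  }
  for (int c = 0; c < n; ++c)
    q += sum_in[c] / two_m - (sum_tot[c] / two_m) * (sum_tot[c] / two_m);
  return q;
}

// One Louvain pass: local moving on the current (possibly aggregated) graph.
// Returns true if any node moved.
static bool louvain_local_move(const std::vector<std::vector<std::pair<int,double>>> &nbw,
                               const std::vector<double> &deg, double two_m,
                               std::vector<int> &memb, std::mt19937_64 &rng) {
  int n = (int) nbw.size();
  std::vector<double> ctot(n, 0.0);
  for (int i = 0; i < n; ++i) ctot[memb[i]] += deg[i];
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::shuffle(order.begin(), order.end(), rng);
  bool moved_any = false, improved = true;
  std::vector<double> wsum(n, 0.0);
  while (improved) {
    improved = false;
    for (int idx = 0; idx < n; ++idx) {
      int v = order[idx];
      int cv = memb[v];
      std::vector<int> touched;
      for (auto &pw : nbw[v]) {
        int c = memb[pw.first];
        if (wsum[c] == 0.0) touched.push_back(c);
        wsum[c] += pw.second;
      }
      ctot[cv] -= deg[v];
      double best_gain = wsum[cv] - ctot[cv] * deg[v] / two_m;
      int best_c = cv;
      for (int c : touched) {
        if (c == cv) continue;
        double gain = wsum[c] - ctot[c] * deg[v] / two_m;
        if (gain > best_gain + 1e-12) { best_gain = gain; best_c = c; }
      }
      ctot[best_c] += deg[v];
      if (best_c != cv) { memb[v] = best_c; improved = true; moved_any = true; }
      for (int c : touched) wsum[c] = 0.0;
      if (wsum[cv] != 0.0) wsum[cv] = 0.0;
    }
  }
  return moved_any;
}

// Post-Louvain refinement on the original graph: alternate best single-node
// moves (to any community, or isolation) and best community merges until no
// move improves Q. Cheap at these graph sizes and removes most of the local
// optima a greedy aggregation pass can stall in.
static void refine_partition(const std::vector<std::vector<int>> &nb,
                             const std::vector<double> &deg, double two_m,
                             std::vector<int> &memb) {
  int n = (int) nb.size();
  bool improved = true;
  while (improved) {
    improved = false;
    // single-node moves
    for (int v = 0; v < n; ++v) {
      std::vector<double> tot(n, 0.0), kvc(n, 0.0);
      for (int i = 0; i < n; ++i) tot[memb[i]] += deg[i];
      for (int w : nb[v]) kvc[memb[w]] += 1.0;
      int a = memb[v];
      double ka = kvc[a];
      double tota = tot[a] - deg[v];
      // candidate targets: neighbour communities and an empty community
      int empty = -1;
      for (int c = 0; c < n; ++c) if (tot[c] == 0.0) { empty = c; break; }
      double best_dq = 1e-12;
      int best_c = a;
      for (int c = 0; c < n; ++c) {
        if (c == a || (kvc[c] == 0.0 && c != empty)) continue;
        double dq = (kvc[c] - ka) / (two_m / 2.0) -
          (2.0 * deg[v] * tot[c] + deg[v] * deg[v] -
           2.0 * deg[v] * tota + deg[v] * deg[v]) / (two_m * two_m);
        if (dq > best_dq) { best_dq = dq; best_c = c; }
      }
      if (best_c != a) { memb[v] = best_c; improved = true; }
    }
    // community merges
    std::vector<double> tot(n, 0.0);
    for (int i = 0; i < n; ++i) tot[memb[i]] += deg[i];
    std::vector<std::vector<double>> wcd(n, std::vector<double>(n, 0.0));
    for (int i = 0; i < n; ++i)
      for (int j : nb[i]) wcd[memb[i]][memb[j]] += 1.0;
    double best_dq = 1e-12;
    int bc = -1, bd = -1;
    for (int c = 0; c < n; ++c) {
      if (tot[c] == 0.0) continue;
      for (int d = c + 1; d < n; ++d) {
        if (tot[d] == 0.0) continue;
        double dq = wcd[c][d] / two_m - 2.0 * tot[c] * tot[d] /
          (two_m * two_m);
        if (dq > best_dq) { best_dq = dq; bc = c; bd = d; }
      }
    }
    if (bc >= 0) {
      for (int i = 0; i < n; ++i) if (memb[i] == bd) memb[i] = bc;
      improved = true;
    }
  }
}

// Louvain with aggregation, multiple seeded restarts; returns best Q and
// its membership (0-based community ids, relabelled consecutively).
// [[Rcpp::export(name = ".cpp_louvain")]]
List cpp_louvain(const IntegerMatrix &A, int restarts, double seed) {
  int n = A.nrow();
  std::vector<std::vector<int>> nb = adj_list(A);
  std::vector<double> deg(n, 0.0);
  double two_m = 0.0;
  for (int i = 0; i < n; ++i) { deg[i] = (double) nb[i].size(); two_m += deg[i]; }
  if (two_m <= 0.0)
    return List::create(_["Q"] = NA_REAL, _["membership"] = IntegerVector(n));

  double best_q = -1.0;
  std::vector<int> best_memb(n);
  std::mt19937_64 rng((uint64_t) seed);

  for (int r = 0; r < restarts; ++r) {
    // level-0 weighted graph = input
    std::vector<std::vector<std::pair<int,double>>> nbw(n);
    for (int i = 0; i < n; ++i)
      for (int j : nb[i]) nbw[i].push_back({j, 1.0});
    std::vector<double> d = deg;
    std::vector<int> node_of(n);           // community of each original node
    for (int i = 0; i < n; ++i) node_of[i] = i;

    bool more = true;
    bool first_level = true;
    while (more) {
      int nn = (int) nbw.size();
      std::vector<int> memb(nn);
      for (int i = 0; i < nn; ++i) memb[i] = i;
      // restarts after the first explore from random coarse partitions,
      // which escapes local optima the all-singletons start converges to
      if (first_level && r > 0) {
        std::uniform_int_distribution<int> lab(0, std::max(1, nn / 2) - 1);
        for (int i = 0; i < nn; ++i) memb[i] = lab(rng);
      }
      first_level = false;
      more = louvain_local_move(nbw, d, two_m, memb, rng);
      // relabel communities consecutively
      std::vector<int> remap(nn, -1);
      int nc = 0;
      for (int i = 0; i < nn; ++i) if (remap[memb[i]] < 0) remap[memb[i]] = nc++;
      for (int i = 0; i < nn; ++i) memb[i] = remap[memb[i]];
      for (int i = 0; i < n; ++i) node_of[i] = memb[node_of[i]];
      if (!more || nc == nn) break;
      // aggregate
      std::vector<std::vector<std::pair<int,double>>> agg(nc);
      std::vector<std::vector<double>> wacc(nc, std::vector<double>(nc, 0.0));
      for (int i = 0; i < nn; ++i)
        for (auto &pw : nbw[i]) wacc[memb[i]][memb[pw.first]] += pw.second;
      std::vector<double> dn(nc, 0.0);
      for (int c = 0; c < nc; ++c) {
        for (int c2 = 0; c2 < nc; ++c2) {
          if (wacc[c][c2] > 0.0 && c2 != c) agg[c].push_back({c2, wacc[c][c2]});
          dn[c] += wacc[c][c2];
        }
        // self-loop weight counts twice in degree already via wacc[c][c]
      }
      // keep self-loops as part of degree: dn[c] = sum of all incident weight
      nbw = agg;
      d = dn;
      // self-loop internal weight is handled implicitly: local_move gain uses
      // neighbour weights only, aggregated self-weight stays internal
    }
    refine_partition(nb, deg, two_m, node_of);
    double q = modularity_of(nb, deg, two_m, node_of);
    if (q > best_q) { best_q = q; best_memb = node_of; }
  }
  // consecutive labels
  std::vector<int> remap(n, -1);
  int nc = 0;
  IntegerVector memb_out(n);
  for (int i = 0; i < n; ++i) {
    if (remap[best_memb[i]] < 0) remap[best_memb[i]] = nc++;
    memb_out[i] = remap[best_memb[i]];
  }
  return List::create(_["Q"] = best_q, _["membership"] = memb_out);
}
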