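// Bounded path search and segment chaining over the oriented-node adjacency
// of an allele graph. The adjacency (with per-oriented-node effective and
// overlap expanded lengths) is held in an external pointer built once per
// aligner; single-source shortest-distance results are cached inside it.

#include <Rcpp.h>
#include <vector>
#include <map>
#include <queue>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

struct DijkstraRes {
  std::vector<double> dist;
  std::vector<int> parent; // 0 = none
  double reentry;
  int reentry_via;         // 0 = none
};

struct GraphAdj {
  int n;
  std::vector<std::vector<int> > adj; // 1-based oriented indices
  std::vector<double> eff;            // effective expanded length
  std::vector<double> ov;             // leading-overlap expanded length
  double cutoff;
  std::map<int, DijkstraRes> cache;
};

static const DijkstraRes& dijkstra_cached(GraphAdj* g, int src) {
  std::map<int, DijkstraRes>::iterator it = g->cache.find(src);
  if (it != g->cache.end()) return it->second;
  DijkstraRes res;
  res.dist.assign(g->n + 1, R_PosInf);
  res.parent.assign(g->n + 1, 0);
  typedef std::pair<double, int> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  res.dist[src] = 0;
  pq.push(std::make_pair(0.0, src));
  while (!pq.empty()) {
    QE top = pq.top(); pq.pop();
    if (top.first > res.dist[top.second]) continue;
    const std::vector<int>& nbs = g->adj[top.second];
    for (size_t t = 0; t < nbs.size(); ++t) {
      int v = nbs[t];
      double nd = top.first + g->eff[v];
      if (nd <= g->cutoff && nd < res.dist[v]) {
        res.dist[v] = nd;
        res.parent[v] = top.second;
        pq.push(std::make_pair(nd, v));
      }
    }
  }
  res.reentry = R_PosInf;
  res.reentry_via = 0;
  for (int u = 1; u <= g->n; ++u) {
    if (!R_finite(res.dist[u])) continue;
    const std::vector<int>& nbs = g->adj[u];
    if (std::find(nbs.begin(), nbs.end(), src) != nbs.end()) {
      double cand = res.dist[u] + g->eff[src];
      if (cand < res.reentry) { res.reentry = cand; res.reentry_via = u; }
    }
  }
  g->cache[src] = res;
  return g->cache[src];
}

// [[Rcpp::export]]
SEXP cpp_graph_adj(List adj_to, NumericVector eff, NumericVector ov,
                   double cutoff = 6000) {
  GraphAdj* g = new GraphAdj();
  g->n = adj_to.size();
  g->adj.resize(g->n + 1);
  g->eff.assign(g->n + 1, 0.0);
  g->ov.assign(g->n + 1, 0.0);
  g->cutoff = cutoff;
  for (int i = 0; i < g->n; ++i) {
    if (!Rf_isNull(adj_to[i])) {
      IntegerVector v = adj_to[i];
      g->adj[i + 1].assign(v.begin(), v.end());
    }
    g->eff[i + 1] = eff[i];
    g->ov[i + 1] = ov[i];
  }
  XPtr<GraphAdj> p(g, true);
  return p;
}

// candidate paths from the successors of `from` to `to` (target included),
// enumerated shortest-first (uniform-cost search over cumulative effective
// expanded length), bounded by `budget` and a step cap. Shortest-first
// ordering makes the candidate set the plausible alternative alleles rather
// than arbitrary deep detours.
// [[Rcpp::export]]
List cpp_enum_gap_paths(SEXP ptr, int from, int to, double budget,
                        int max_paths = 8, int max_steps = 4000) {
  XPtr<GraphAdj> g(ptr);
  std::vector<std::vector<int> > results;
  struct Node { std::vector<int> path; int at; double len; };
  typedef std::pair<double, int> QK; // (len, state index) — min-heap
  std::vector<Node> pool;
  std::priority_queue<QK, std::vector<QK>, std::greater<QK> > pq;
  Node s0; s0.at = from; s0.len = 0;
  pool.push_back(s0);
  pq.push(std::make_pair(0.0, 0));
  int steps = 0;
  while (!pq.empty() && (int)results.size() < max_paths && steps < max_steps) {
    ++steps;
    int ci = pq.top().second; pq.pop();
    Node cur = pool[ci];
    const std::vector<int>& nbs = g->adj[cur.at];
    for (size_t t = 0; t < nbs.size(); ++t) {
      int v = nbs[t];
      double nlen = cur.len + g->eff[v];
      if (v == to) {
        std::vector<int> p = cur.path;
        p.push_back(v);
        results.push_back(p);
        if ((int)results.size() >= max_paths) break;
        continue;
      }
      if (nlen > budget) continue;
      Node nx; nx.path = cur.path; nx.path.push_back(v);
      nx.at = v; nx.len = nlen;
      pool.push_back(nx);
      pq.push(std::make_pair(nlen, (int)pool.size() - 1));
    }
  }
  List out(results.size());
  for (size_t i = 0; i < results.size(); ++i) out[i] = wrap(results[i]);
  return out;
}

// [[Rcpp::export]]
List cpp_dijkstra(SEXP ptr, int src) {
  XPtr<GraphAdj> g(ptr);
  const DijkstraRes& res = dijkstra_cached(g.get(), src);
  const int n = g->n;
  NumericVector d(n); IntegerVector par(n);
  for (int i = 0; i < n; ++i) {
    d[i] = res.dist[i + 1];
    par[i] = res.parent[i + 1] == 0 ? NA_INTEGER : res.parent[i + 1];
  }
  return List::create(_["dist"] = d, _["parent"] = par,
                      _["reentry"] = res.reentry,
                      _["reentry_via"] = res.reentry_via == 0 ? NA_INTEGER :
                        res.reentry_via);
}

// Colinear chaining over anchor segments (0-based read coords; oi are
// 1-based oriented node indices). Returns best-predecessor arrays:
// link 0 = chain start, 1 = same-node continuation, 2 = graph path.
// `active` marks segments still available (1) or consumed (0).
// [[Rcpp::export]]
List cpp_chain_segments(SEXP ptr, IntegerVector rs, IntegerVector re,
                        IntegerVector oi, IntegerVector qs, IntegerVector qe,
                        NumericVector na_, NumericVector tail_,
                        NumericVector exp_oi_unused, IntegerVector active,
                        int ak, int max_gap = 3000, int max_cand = 120) {
  XPtr<GraphAdj> g(ptr);
  const int ns = rs.size();
  NumericVector score(ns, R_NegInf);
  IntegerVector pred(ns, 0);
  IntegerVector link(ns, 0);
  std::vector<int> act;
  for (int i = 0; i < ns; ++i) if (active[i]) act.push_back(i);
  for (size_t aj = 0; aj < act.size(); ++aj) {
    const int jj = act[aj];
    score[jj] = na_[jj];
    // candidate predecessors: most recent first, bounded
    int tried = 0;
    for (int ai = (int)aj - 1; ai >= 0 && tried < max_cand; --ai) {
      const int ii = act[ai];
      if (re[ii] >= re[jj]) continue;
      if (re[ii] > rs[jj] + 100) continue;
      if (re[ii] < rs[jj] - max_gap) break; // sorted by rs; nothing closer left
      ++tried;
      const double gap_r = rs[jj] - (re[ii] + ak);
      double gap_g = NA_REAL;
      int how = 0;
      if (oi[ii] == oi[jj] && qs[jj] >= qe[ii]) {
        gap_g = qs[jj] - (qe[ii] + ak);
        how = 1;
      }
      if (!R_finite(gap_g) || std::fabs(gap_r - gap_g) > 60) {
        const double head_budget = gap_r - tail_[ii] + 500 + 0.3 * std::max(gap_r, 0.0);
        if (head_budget >= 0) {
          const DijkstraRes& dj = dijkstra_cached(g.get(), oi[ii]);
          double dk;
          if (oi[jj] == oi[ii]) dk = dj.reentry;
          else dk = dj.dist[oi[jj]];
          if (R_finite(dk)) {
            const double inter = dk - g->eff[oi[jj]];
            const double g2 = tail_[ii] + inter + (qs[jj] - g->ov[oi[jj]]);
            if (!R_finite(gap_g) ||
                std::fabs(gap_r - g2) < std::fabs(gap_r - gap_g)) {
              gap_g = g2;
              how = 2;
            }
          }
        }
      }
      if (!R_finite(gap_g)) continue;
      const double diff = std::fabs(gap_r - gap_g);
      if (diff > 500 + 0.2 * std::max(gap_r, 0.0)) continue;
      const double sc = score[ii] + na_[jj] - 0.1 * diff;
      if (sc > score[jj]) { score[jj] = sc; pred[jj] = ii + 1; link[jj] = how; }
    }
  }
  return List::create(_["score"] = score, _["pred"] = pred, _["link"] = link);
}
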