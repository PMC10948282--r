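// Base-level sequence-to-graph alignment for gap threading: edit-distance
// Dijkstra over the product of the read substring and the local graph
// neighbourhood. Used to fill the region between two anchored segments with
// the graph path that truly matches the read, rather than ranking a handful
// of enumerated candidate paths.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
#include <queue>
#include <unordered_map>
using namespace Rcpp;

// oriented node sequences are registered once per aligner
struct GapGraph {
  int n;
  std::vector<std::vector<int> > adj;
  std::vector<std::string> seq;   // oriented expanded sequence, 1-based
  std::vector<int> ov;            // leading-overlap expanded length
};

// [[Rcpp::export]]
SEXP cpp_gap_graph(List adj_to, CharacterVector node_exp_oi, IntegerVector ov) {
  GapGraph* g = new GapGraph();
  g->n = adj_to.size();
  g->adj.resize(g->n + 1);
  g->seq.resize(g->n + 1);
  g->ov.assign(g->n + 1, 0);
  for (int i = 0; i < g->n; ++i) {
    if (!Rf_isNull(adj_to[i])) {
      IntegerVector v = adj_to[i];
      g->adj[i + 1].assign(v.begin(), v.end());
    }
    g->seq[i + 1] = as<std::string>(node_exp_oi[i]);
    g->ov[i + 1] = ov[i];
  }
  XPtr<GapGraph> p(g, true);
  return p;
}

// state: oriented node, consumed position within it, consumed read length
struct GapState { int oi; int pos; int rp; };

// bit 63: whether at least one edge has been crossed (needed so a gap whose
// source and target are the same oriented node must actually leave it)
static inline uint64_t skey(int oi, int pos, int rp, int moved) {
  return ((uint64_t)(uint32_t)moved << 63) | ((uint64_t)oi << 40) |
         ((uint64_t)(uint32_t)pos << 20) | (uint32_t)rp;
}

// Align `read` from the end of (from_oi, from_pos) to (to_oi, to_pos).
// Returns dist = -1 if no alignment within `limit`, otherwise the edit
// distance and the list of oriented nodes entered (target included,
// source excluded).
// [[Rcpp::export]]
List cpp_align_gap(SEXP ptr, int from_oi, int from_pos, int to_oi, int to_pos,
                   std::string read, int limit, int max_states = 2000000) {
  XPtr<GapGraph> g(ptr);
  const int L = (int)read.size();
  typedef std::pair<double, uint64_t> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  struct Entry { int dist; uint64_t parent; int entered; };
  std::unordered_map<uint64_t, Entry> tab;
  tab.reserve(1 << 14);

  const int target_cap = std::max(to_pos, g->ov[to_oi]);
  uint64_t s0 = skey(from_oi, from_pos, 0, 0);
  Entry e0; e0.dist = 0; e0.parent = s0; e0.entered = 0;
  tab[s0] = e0;
  pq.push(std::make_pair(0.0, s0));
  int steps = 0;
  uint64_t goal = 0;
  bool found = false;

  while (!pq.empty() && steps < max_states) {
    ++steps;
    QE top = pq.top(); pq.pop();
    int d = (int)top.first;
    uint64_t key = top.second;
    std::unordered_map<uint64_t, Entry>::iterator it = tab.find(key);
    if (it == tab.end() || d > it->second.dist) continue;
    int moved = (int)(key >> 63);
    int oi = (int)((key >> 40) & 0x7FFFFF);
    int pos = (int)((key >> 20) & 0xFFFFF);
    int rp = (int)(key & 0xFFFFF);
    if (oi == to_oi && moved && pos >= target_cap && rp == L) {
      goal = key; found = true; break;
    }
    if (d > limit) break;
    const std::string& s = g->seq[oi];
    const bool in_target = (oi == to_oi && moved);
    const int node_end = in_target ? target_cap : (int)s.size();
    // relax helper
    #define RELAX(noi, npos, nrp, nd, ent, nmoved) do { \
      uint64_t nk = skey((noi), (npos), (nrp), (nmoved)); \
      std::unordered_map<uint64_t, Entry>::iterator jt = tab.find(nk); \
      if (jt == tab.end() || (nd) < jt->second.dist) { \
        Entry ne; ne.dist = (nd); ne.parent = key; ne.entered = (ent); \
        tab[nk] = ne; \
        pq.push(std::make_pair((double)(nd), nk)); \
      } } while (0)
    if (pos < node_end) {
      if (rp < L) {
        int c = (s[pos] == read[rp]) ? 0 : 1;
        RELAX(oi, pos + 1, rp + 1, d + c, 0, moved);     // (mis)match
      }
      RELAX(oi, pos + 1, rp, d + 1, 0, moved);           // deletion in read
    }
    if (rp < L) RELAX(oi, pos, rp + 1, d + 1, 0, moved); // insertion in read
    if (pos >= node_end && !in_target) {
      const std::vector<int>& nbs = g->adj[oi];
      for (size_t t = 0; t < nbs.size(); ++t) {
        int v = nbs[t];
        int entry = (v == to_oi) ? std::min(g->ov[v], target_cap) : g->ov[v];
        RELAX(v, entry, rp, d, v, 1);
      }
    }
    #undef RELAX
  }
  if (!found) return List::create(_["dist"] = -1);
  // reconstruct entered-node sequence
  std::vector<int> nodes;
  uint64_t cur = goal;
  while (cur != s0) {
    const Entry& e = tab[cur];
    if (e.entered) nodes.push_back(e.entered);
    cur = e.parent;
  }
  std::reverse(nodes.begin(), nodes.end());
  return List::create(_["dist"] = tab[goal].dist, _["path"] = wrap(nodes));
}
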