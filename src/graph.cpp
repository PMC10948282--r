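// Homopolymer-compressed de Bruijn unitig graph ("allele graph") builder.
//
// Input reads are already homopolymer-compressed; per-read run-length vectors
// travel alongside so that per-position run-length observations can be
// accumulated onto the unitigs (median taken at the end).
//
// Conventions: a k-mer's canonical form is min(kmer, revcomp). Orientation
// dir 0 = canonical as written, 1 = reverse complement. Unitigs are maximal
// non-branching paths of solid k-mers; a unitig's stored sequence is the
// lexicographic minimum of its two strands. Node ids are assigned by sorted
// sequence, which makes graph construction independent of read order.

#include <Rcpp.h>
#include <string>
#include <vector>
#include <map>
#include <unordered_map>
#include <algorithm>
using namespace Rcpp;

static inline char comp(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G';
  case 'G': return 'C'; case 'T': return 'A';
  default: return 'N';
  }
}
static std::string rc(const std::string& s) {
  std::string r(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i) r[i] = comp(s[s.size() - 1 - i]);
  return r;
}
static inline bool valid_base(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

struct OKmer { int id; int dir; };
static inline bool operator==(const OKmer& a, const OKmer& b) {
  return a.id == b.id && a.dir == b.dir;
}

// [[Rcpp::export]]
List cpp_build_dbg(CharacterVector seqs, List runs, int k, int solid_min) {
  const int n_reads = seqs.size();
  std::vector<std::string> reads(n_reads);
  for (int i = 0; i < n_reads; ++i) reads[i] = as<std::string>(seqs[i]);

  // ---- pass 1: count canonical k-mers ----
  std::unordered_map<std::string, int> counts;
  for (int r = 0; r < n_reads; ++r) {
    const std::string& s = reads[r];
    if ((int)s.size() < k) continue;
    int run = 0;
    for (size_t i = 0; i < s.size(); ++i) {
      if (valid_base(s[i])) ++run; else run = 0;
      if (run >= k) {
        std::string f = s.substr(i - k + 1, k);
        std::string v = rc(f);
        ++counts[f <= v ? f : v];
      }
    }
    if (r % 64 == 0) Rcpp::checkUserInterrupt();
  }

  // ---- solid set, ids in sorted k-mer order ----
  std::vector<std::string> solid;
  for (std::unordered_map<std::string, int>::iterator it = counts.begin();
       it != counts.end(); ++it)
    if (it->second >= solid_min) solid.push_back(it->first);
  std::sort(solid.begin(), solid.end());
  const int nk = (int)solid.size();
  if (nk == 0) stop("no solid k-mers: lower solid_min or check input reads");
  std::unordered_map<std::string, int> kid;
  kid.reserve(nk * 2);
  std::vector<int> kcount(nk);
  for (int i = 0; i < nk; ++i) { kid[solid[i]] = i; kcount[i] = counts[solid[i]]; }

  // ---- pass 2: k-mer level adjacency and edge counts ----
  // nexts[2*id + dir] = distinct oriented successors of (id, dir)
  std::vector<std::vector<OKmer> > nexts(2 * (size_t)nk);
  std::map<std::vector<int>, int> edge_count; // normalized (a,da,b,db) -> count
  std::vector<std::vector<std::pair<int, int> > > occ(n_reads); // (pos, 2*id+dir) solid occurrences

  for (int r = 0; r < n_reads; ++r) {
    const std::string& s = reads[r];
    if ((int)s.size() < k) continue;
    int run = 0, prev_id = -1, prev_dir = 0, prev_pos = -2;
    for (size_t i = 0; i < s.size(); ++i) {
      if (valid_base(s[i])) ++run; else run = 0;
      if (run < k) { continue; }
      int pos = (int)i - k + 1;
      std::string f = s.substr(pos, k);
      std::string v = rc(f);
      bool fwd = f <= v;
      std::unordered_map<std::string, int>::iterator it = kid.find(fwd ? f : v);
      if (it == kid.end()) { prev_pos = -2; continue; }
      int id = it->second, dir = fwd ? 0 : 1;
      occ[r].push_back(std::make_pair(pos, 2 * id + dir));
      if (prev_pos == pos - 1) {
        // edge (prev_id, prev_dir) -> (id, dir); normalize with its rc twin
        std::vector<int> e1(4), e2(4);
        e1[0] = prev_id; e1[1] = prev_dir; e1[2] = id;      e1[3] = dir;
        e2[0] = id;      e2[1] = 1 - dir;  e2[2] = prev_id; e2[3] = 1 - prev_dir;
        ++edge_count[e1 <= e2 ? e1 : e2];
        OKmer fw; fw.id = id; fw.dir = dir;
        OKmer bw; bw.id = prev_id; bw.dir = 1 - prev_dir;
        std::vector<OKmer>& vf = nexts[2 * (size_t)prev_id + prev_dir];
        if (std::find(vf.begin(), vf.end(), fw) == vf.end()) vf.push_back(fw);
        std::vector<OKmer>& vb = nexts[2 * (size_t)id + (1 - dir)];
        if (std::find(vb.begin(), vb.end(), bw) == vb.end()) vb.push_back(bw);
      }
      prev_id = id; prev_dir = dir; prev_pos = pos;
    }
    if (r % 64 == 0) Rcpp::checkUserInterrupt();
  }

  // ---- unitig compaction ----
  // mergeable step x->y: nexts(x) == {y} and nexts(reverse y) == {reverse x}
  std::vector<int> uni_of(nk, -1), pos_in(nk, 0), dir_in(nk, 0);
  std::vector<std::vector<OKmer> > unitigs;
  std::vector<bool> visited(nk, false);
  for (int start = 0; start < nk; ++start) {
    if (visited[start]) continue;
    std::vector<OKmer> path;
    OKmer s0; s0.id = start; s0.dir = 0;
    path.push_back(s0);
    visited[start] = true;
    // extend forward
    for (;;) {
      OKmer x = path.back();
      const std::vector<OKmer>& nx = nexts[2 * (size_t)x.id + x.dir];
      if (nx.size() != 1) break;
      OKmer y = nx[0];
      const std::vector<OKmer>& py = nexts[2 * (size_t)y.id + (1 - y.dir)];
      if (py.size() != 1) break;
      if (visited[y.id]) break; // includes closing a cycle back to start
      path.push_back(y);
      visited[y.id] = true;
    }
    // extend backward from the front (walk the reverse strand forward)
    for (;;) {
      OKmer x = path.front();
      const std::vector<OKmer>& px = nexts[2 * (size_t)x.id + (1 - x.dir)];
      if (px.size() != 1) break;
      OKmer y = px[0]; // oriented predecessor on the reverse strand
      const std::vector<OKmer>& qy = nexts[2 * (size_t)y.id + (1 - y.dir)];
      if (qy.size() != 1) break;
      if (visited[y.id]) break;
      OKmer yf; yf.id = y.id; yf.dir = 1 - y.dir; // flip back to forward strand
      path.insert(path.begin(), yf);
      visited[y.id] = true;
    }
    unitigs.push_back(path);
  }

  // ---- unitig sequences, canonical strand ----
  const int nu = (int)unitigs.size();
  std::vector<std::string> useq(nu);
  std::vector<double> ucov(nu);
  for (int u = 0; u < nu; ++u) {
    std::vector<OKmer>& p = unitigs[u];
    std::string s = p[0].dir == 0 ? solid[p[0].id] : rc(solid[p[0].id]);
    double cv = kcount[p[0].id];
    for (size_t i = 1; i < p.size(); ++i) {
      const std::string km = p[i].dir == 0 ? solid[p[i].id] : rc(solid[p[i].id]);
      s.push_back(km[k - 1]);
      cv += kcount[p[i].id];
    }
    std::string v = rc(s);
    if (v < s) {
      s = v;
      std::reverse(p.begin(), p.end());
      for (size_t i = 0; i < p.size(); ++i) p[i].dir = 1 - p[i].dir;
    }
    useq[u] = s;
    ucov[u] = cv / (double)p.size();
  }

  // deterministic ids: sort unitigs by sequence
  std::vector<int> order(nu);
  for (int i = 0; i < nu; ++i) order[i] = i;
  std::sort(order.begin(), order.end(),
            [&useq](int a, int b) { return useq[a] < useq[b]; });
  std::vector<int> rank(nu);
  for (int i = 0; i < nu; ++i) rank[order[i]] = i;

  for (int u = 0; u < nu; ++u) {
    const std::vector<OKmer>& p = unitigs[u];
    for (size_t i = 0; i < p.size(); ++i) {
      uni_of[p[i].id] = rank[u];
      pos_in[p[i].id] = (int)i;
      dir_in[p[i].id] = p[i].dir;
    }
  }

  std::vector<std::string> useq2(nu);
  std::vector<double> ucov2(nu);
  std::vector<int> ulen(nu); // number of constituent k-mers
  for (int u = 0; u < nu; ++u) {
    useq2[rank[u]] = useq[u];
    ucov2[rank[u]] = ucov[u];
    ulen[rank[u]] = (int)unitigs[u].size();
  }

  // ---- unitig-level edges from terminal k-mer adjacencies ----
  std::map<std::vector<int>, double> uedges; // (u, ou, v, ov) 0-based, 0='+'
  for (std::map<std::vector<int>, int>::iterator it = edge_count.begin();
       it != edge_count.end(); ++it) {
    int a = it->second ? it->first[0] : it->first[0];
    int da = it->first[1], b = it->first[2], db = it->first[3];
    a = it->first[0];
    int ua = uni_of[a], ub = uni_of[b];
    int pa = pos_in[a], pb = pos_in[b];
    bool a_fwd = (da == dir_in[a]); // traversing unitig ua forward?
    bool b_fwd = (db == dir_in[b]);
    bool a_term = a_fwd ? (pa == ulen[ua] - 1) : (pa == 0);
    bool b_term = b_fwd ? (pb == 0) : (pb == ulen[ub] - 1);
    if (!a_term || !b_term) continue; // interior adjacency within a unitig
    std::vector<int> e1(4), e2(4);
    e1[0] = ua; e1[1] = a_fwd ? 0 : 1; e1[2] = ub; e1[3] = b_fwd ? 0 : 1;
    e2[0] = ub; e2[1] = b_fwd ? 1 : 0; e2[2] = ua; e2[3] = a_fwd ? 1 : 0;
    uedges[e1 <= e2 ? e1 : e2] += (double)it->second;
  }

  // ---- run-length observations: histogram per unitig position over every
  // offset of every supporting k-mer occurrence (bins 1..31, 32 = overflow)
  const int NB = 32;
  std::vector<std::vector<uint32_t> > hist(nu);
  std::vector<int> ubase(nu);
  for (int u = 0; u < nu; ++u) hist[u].assign((size_t)(ulen[u] + k - 1) * NB, 0);
  for (int r = 0; r < n_reads; ++r) {
    IntegerVector rr = runs[r];
    for (size_t q = 0; q < occ[r].size(); ++q) {
      int pos = occ[r][q].first;
      int id = occ[r][q].second / 2, dir = occ[r][q].second % 2;
      int u = uni_of[id], pa = pos_in[id];
      bool fwd = (dir == dir_in[id]);
      uint32_t* h = &hist[u][0];
      for (int t = 0; t < k; ++t) {
        int upos = fwd ? pa + t : pa + k - 1 - t;
        int rl = rr[pos + t];
        if (rl < 1) rl = 1; else if (rl > NB) rl = NB;
        ++h[(size_t)upos * NB + (rl - 1)];
      }
    }
  }
  List runs_out(nu);
  for (int u = 0; u < nu; ++u) {
    int L = ulen[u] + k - 1;
    IntegerVector med(L);
    for (int p = 0; p < L; ++p) {
      const uint32_t* h = &hist[u][(size_t)p * NB];
      uint64_t tot = 0;
      for (int b = 0; b < NB; ++b) tot += h[b];
      if (tot == 0) { med[p] = 1; continue; }
      uint64_t half = (tot + 1) / 2, acc = 0;
      int m1 = 1;
      for (int b = 0; b < NB; ++b) { acc += h[b]; if (acc >= half) { m1 = b + 1; break; } }
      med[p] = m1;
    }
    runs_out[u] = med;
  }

  // ---- assemble result ----
  const int ne = (int)uedges.size();
  IntegerVector ef(ne), et(ne);
  CharacterVector efo(ne), eto(ne);
  NumericVector ecov(ne);
  int i = 0;
  for (std::map<std::vector<int>, double>::iterator it = uedges.begin();
       it != uedges.end(); ++it, ++i) {
    ef[i] = it->first[0] + 1;
    efo[i] = it->first[1] == 0 ? "+" : "-";
    et[i] = it->first[2] + 1;
    eto[i] = it->first[3] == 0 ? "+" : "-";
    ecov[i] = it->second;
  }
  return List::create(
    _["seq"] = wrap(useq2), _["cov"] = wrap(ucov2), _["runs"] = runs_out,
    _["edge_from"] = ef, _["edge_from_o"] = efo,
    _["edge_to"] = et, _["edge_to_o"] = eto, _["edge_cov"] = ecov);
}
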