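// Exact k-mer anchoring of reads against expanded allele-graph node
// sequences, with collapsing of colinear anchors into diagonal segments.
// anchor_k must be <= 31 (2-bit packed rolling codes).

#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <vector>
#include <unordered_map>
#include <algorithm>
using namespace Rcpp;

static inline int bcode(char c) {
  switch (c) {
  case 'A': return 0; case 'C': return 1;
  case 'G': return 2; case 'T': return 3;
  default: return -1;
  }
}

struct Hit { int node; int pos; };

struct AnchorIndexC {
  int k;
  std::unordered_map<uint64_t, std::vector<Hit> > map;
};

static void roll_kmers(const std::string& s, int k,
                       void (*cb)(uint64_t, int, void*), void* ud) {
  uint64_t code = 0;
  const uint64_t mask = (k == 32) ? ~(uint64_t)0 : (((uint64_t)1 << (2 * k)) - 1);
  int run = 0;
  for (size_t i = 0; i < s.size(); ++i) {
    int c = bcode(s[i]);
    if (c < 0) { run = 0; code = 0; continue; }
    code = ((code << 2) | (uint64_t)c) & mask;
    if (++run >= k) cb(code, (int)i - k + 1, ud);
  }
}

struct BuildCtx { AnchorIndexC* idx; int node; int max_per_kmer; };
static void build_cb(uint64_t code, int pos, void* ud) {
  BuildCtx* ctx = (BuildCtx*)ud;
  std::vector<Hit>& v = ctx->idx->map[code];
  if ((int)v.size() >= ctx->max_per_kmer) return; // repetitive k-mer, truncated
  Hit h; h.node = ctx->node; h.pos = pos;
  v.push_back(h);
}

// Build an anchor index over node sequences; returned as an external pointer.
// [[Rcpp::export]]
SEXP cpp_anchor_index(CharacterVector node_seqs, int k, int max_per_kmer = 16) {
  if (k < 5 || k > 31) stop("anchor k must be in [5, 31]");
  AnchorIndexC* idx = new AnchorIndexC();
  idx->k = k;
  for (int i = 0; i < node_seqs.size(); ++i) {
    BuildCtx ctx; ctx.idx = idx; ctx.node = i + 1; ctx.max_per_kmer = max_per_kmer;
    roll_kmers(as<std::string>(node_seqs[i]), k, build_cb, &ctx);
  }
  XPtr<AnchorIndexC> p(idx, true);
  return p;
}

struct RawAnchor { int node; int dir; long long diag; int rpos; int npos;
                   double w; };
static bool anchor_lt(const RawAnchor& a, const RawAnchor& b) {
  if (a.node != b.node) return a.node < b.node;
  if (a.dir != b.dir) return a.dir < b.dir;
  if (a.diag != b.diag) return a.diag < b.diag;
  return a.rpos < b.rpos;
}

struct QueryCtx {
  AnchorIndexC* idx;
  std::vector<RawAnchor>* out;
  int max_hits_per_pos;
  int k;
};
static void query_cb(uint64_t code, int pos, void* ud) {
  QueryCtx* ctx = (QueryCtx*)ud;
  int taken = 0;
  const size_t first = ctx->out->size();
  // forward orientation
  std::unordered_map<uint64_t, std::vector<Hit> >::iterator it =
    ctx->idx->map.find(code);
  if (it != ctx->idx->map.end()) {
    for (size_t i = 0; i < it->second.size() && taken < ctx->max_hits_per_pos; ++i, ++taken) {
      RawAnchor a;
      a.node = it->second[i].node; a.dir = 1;
      a.rpos = pos; a.npos = it->second[i].pos;
      a.diag = (long long)pos - (long long)a.npos;
      a.w = 1.0;
      ctx->out->push_back(a);
    }
  }
  // reverse complement of the read k-mer
  uint64_t rcode = 0, c = code;
  for (int i = 0; i < ctx->k; ++i) { rcode = (rcode << 2) | (3 - (c & 3)); c >>= 2; }
  it = ctx->idx->map.find(rcode);
  if (it != ctx->idx->map.end()) {
    for (size_t i = 0; i < it->second.size() && taken < ctx->max_hits_per_pos; ++i, ++taken) {
      RawAnchor a;
      a.node = it->second[i].node; a.dir = -1;
      a.rpos = pos; a.npos = it->second[i].pos;
      a.diag = (long long)pos + (long long)a.npos;
      a.w = 1.0;
      ctx->out->push_back(a);
    }
  }
  // weight anchors by the ambiguity of this read position: a k-mer hitting
  // several homologous nodes is less informative than a unique one
  const size_t m = ctx->out->size() - first;
  if (m > 1) {
    for (size_t i = first; i < ctx->out->size(); ++i)
      (*ctx->out)[i].w = 1.0 / (double)m;
  }
}

// All anchors of a read (capped per read position), 0-based coordinates.
// [[Rcpp::export]]
DataFrame cpp_anchor_raw(std::string read, SEXP index_ptr,
                         int max_hits_per_pos = 5) {
  XPtr<AnchorIndexC> idx(index_ptr);
  std::vector<RawAnchor> anchors;
  QueryCtx ctx; ctx.idx = idx.get(); ctx.out = &anchors;
  ctx.max_hits_per_pos = max_hits_per_pos; ctx.k = idx->k;
  roll_kmers(read, idx->k, query_cb, &ctx);
  const int n = (int)anchors.size();
  IntegerVector rp(n), nd(n), np(n), dr(n);
  for (int i = 0; i < n; ++i) {
    rp[i] = anchors[i].rpos; nd[i] = anchors[i].node;
    np[i] = anchors[i].npos; dr[i] = anchors[i].dir;
  }
  return DataFrame::create(
    _["read_pos"] = rp, _["node"] = nd, _["node_pos"] = np,
    _["orient"] = dr, _["stringsAsFactors"] = false);
}

// Anchor one read against the index and collapse colinear anchors into
// segments. Returns a data.frame with 0-based coordinates: read_start /
// read_end and node_start / node_end are the first and last anchor start
// positions (node positions in node-forward coordinates).
// [[Rcpp::export]]
DataFrame cpp_anchor_segments(std::string read, SEXP index_ptr,
                              int max_hits_per_pos = 5,
                              int max_diag_drift = 50,
                              int max_read_gap = 500) {
  XPtr<AnchorIndexC> idx(index_ptr);
  std::vector<RawAnchor> anchors;
  QueryCtx ctx; ctx.idx = idx.get(); ctx.out = &anchors;
  ctx.max_hits_per_pos = max_hits_per_pos; ctx.k = idx->k;
  roll_kmers(read, idx->k, query_cb, &ctx);
  std::sort(anchors.begin(), anchors.end(), anchor_lt);

  std::vector<int> node, dir, rs, re, ns, ne, cnt;
  std::vector<double> wsum;
  size_t i = 0;
  while (i < anchors.size()) {
    size_t j = i + 1;
    while (j < anchors.size() &&
           anchors[j].node == anchors[i].node &&
           anchors[j].dir == anchors[i].dir &&
           anchors[j].diag - anchors[j - 1].diag <= max_diag_drift &&
           anchors[j].rpos - anchors[j - 1].rpos <= max_read_gap)
      ++j;
    // within [i, j): same diagonal band; order by read position
    std::vector<size_t> ord;
    for (size_t q = i; q < j; ++q) ord.push_back(q);
    std::sort(ord.begin(), ord.end(), [&anchors](size_t a, size_t b) {
      return anchors[a].rpos < anchors[b].rpos;
    });
    size_t segs = 0;
    (void)segs;
    size_t s0 = 0;
    for (size_t q = 1; q <= ord.size(); ++q) {
      bool brk = q == ord.size() ||
        anchors[ord[q]].rpos - anchors[ord[q - 1]].rpos > max_read_gap;
      if (!brk) continue;
      const RawAnchor& a0 = anchors[ord[s0]];
      const RawAnchor& a1 = anchors[ord[q - 1]];
      node.push_back(a0.node); dir.push_back(a0.dir);
      rs.push_back(a0.rpos); re.push_back(a1.rpos);
      ns.push_back(a0.npos); ne.push_back(a1.npos);
      cnt.push_back((int)(q - s0));
      double ws = 0;
      for (size_t qq = s0; qq < q; ++qq) ws += anchors[ord[qq]].w;
      wsum.push_back(ws);
      s0 = q;
    }
    i = j;
  }
  return DataFrame::create(
    _["node"] = node, _["orient"] = dir,
    _["read_start"] = rs, _["read_end"] = re,
    _["node_start"] = ns, _["node_end"] = ne,
    _["n_anchors"] = cnt, _["weight"] = wsum,
    _["stringsAsFactors"] = false);
}
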