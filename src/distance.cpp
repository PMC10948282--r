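// Edit-distance and alignment kernels.
//
// cpp_edit_distance: Myers/Hyyro bit-parallel global edit distance with an
// optional threshold (returns -1 when the distance provably exceeds it).
// cpp_align_global: banded global alignment with traceback, used for
// consensus pileups and for coverage/error classification of morph matches.
// cpp_pairwise_dist: threshold-limited all-vs-all distances with a 15-mer
// sketch prefilter.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return 4; // N and anything else: matches nothing
  }
}

// Multi-word bit-parallel edit distance (Hyyro 2003). Pattern a runs along
// the vertical axis, text b along the horizontal. limit < 0 disables the
// early-exit threshold.
static long long myers_ed(const std::string& a, const std::string& b,
                          long long limit) {
  const long long m = (long long)a.size(), n = (long long)b.size();
  if (m == 0) return (limit >= 0 && n > limit) ? -1 : n;
  if (n == 0) return (limit >= 0 && m > limit) ? -1 : m;
  if (limit >= 0 && std::llabs(m - n) > limit) return -1;

  const int W = (int)((m + 63) / 64);
  std::vector<uint64_t> Peq(5 * W, 0);
  for (long long i = 0; i < m; ++i) {
    int c = base_code(a[i]);
    if (c < 4) Peq[c * W + (i >> 6)] |= (uint64_t)1 << (i & 63);
  }
  std::vector<uint64_t> VP(W, ~(uint64_t)0), VN(W, 0);
  const int lastW = W - 1;
  const uint64_t lastBit = (uint64_t)1 << ((m - 1) & 63);

  long long score = m;
  for (long long j = 0; j < n; ++j) {
    const int c = base_code(b[j]);
    const uint64_t* Eqc = (c < 4) ? &Peq[c * W] : NULL;
    int hin = 1; // top boundary of a global alignment: D[0][j]-D[0][j-1] = +1
    for (int w = 0; w < W; ++w) {
      uint64_t Eq = Eqc ? Eqc[w] : 0;
      uint64_t X = Eq;
      if (hin < 0) X |= 1;
      const uint64_t vp = VP[w], vn = VN[w];
      uint64_t D0 = (((X & vp) + vp) ^ vp) | X | vn;
      uint64_t HP = vn | ~(D0 | vp);
      uint64_t HN = vp & D0;
      int hout = 0;
      const uint64_t hi = (w == lastW) ? lastBit : ((uint64_t)1 << 63);
      if (HP & hi) hout = 1; else if (HN & hi) hout = -1;
      HP = (HP << 1); HN = (HN << 1);
      if (hin < 0) HN |= 1; else if (hin > 0) HP |= 1;
      VP[w] = HN | ~(D0 | HP);
      VN[w] = HP & D0;
      hin = hout;
      if (w == lastW) score += hout;
    }
    // score can still drop by at most n-1-j
    if (limit >= 0 && score - (n - 1 - j) > limit) return -1;
  }
  if (limit >= 0 && score > limit) return -1;
  return score;
}

// Bit-parallel edit distance restricted to a block band of width ~limit
// around the main diagonal (any cell on a <=limit path has |i-j| <= limit,
// so out-of-band blocks can be dropped; the +1 boundary entering the first
// active block is an upper-bound boundary condition, exact for d <= limit).
static long long myers_banded(const std::string& a, const std::string& b,
                              long long limit) {
  const long long m = (long long)a.size(), n = (long long)b.size();
  if (limit < 0) return myers_ed(a, b, -1);
  if (std::llabs(m - n) > limit) return -1;
  if (m == 0 || n == 0) return std::max(m, n) <= limit ? std::max(m, n) : -1;
  const int W = (int)((m + 63) / 64);
  std::vector<uint64_t> Peq(5 * W, 0);
  for (long long i = 0; i < m; ++i) {
    int c = base_code(a[i]);
    if (c < 4) Peq[c * W + (i >> 6)] |= (uint64_t)1 << (i & 63);
  }
  std::vector<uint64_t> VP(W, ~(uint64_t)0), VN(W, 0);
  std::vector<long long> bscore(W);
  for (int w = 0; w < W; ++w) bscore[w] = ((long long)w + 1) * 64;
  bscore[W - 1] = m;
  const uint64_t lastBit = (uint64_t)1 << ((m - 1) & 63);
  int first = 0;
  int last = (int)std::min((long long)W - 1, limit / 64 + 1);
  for (long long j = 0; j < n; ++j) {
    const int c = base_code(b[j]);
    // extend the band downward as j grows
    while (last < W - 1 && (long long)(last + 1) * 64 <= j + limit + 1) {
      ++last;
      VP[last] = ~(uint64_t)0; VN[last] = 0;
      bscore[last] = bscore[last - 1] + ((last == W - 1) ? (m - (long long)last * 64)
                                                         : 64);
    }
    // retire blocks fully above the band
    while (first < last && (long long)(first + 1) * 64 < j - limit) ++first;
    int hin = 1;
    for (int w = first; w <= last; ++w) {
      uint64_t Eq = (c < 4) ? Peq[c * W + w] : 0;
      uint64_t X = Eq;
      if (hin < 0) X |= 1;
      const uint64_t vp = VP[w], vn = VN[w];
      uint64_t D0 = (((X & vp) + vp) ^ vp) | X | vn;
      uint64_t HP = vn | ~(D0 | vp);
      uint64_t HN = vp & D0;
      int hout = 0;
      const uint64_t hi = (w == W - 1) ? lastBit : ((uint64_t)1 << 63);
      if (HP & hi) hout = 1; else if (HN & hi) hout = -1;
      HP = (HP << 1); HN = (HN << 1);
      if (hin < 0) HN |= 1; else if (hin > 0) HP |= 1;
      VP[w] = HN | ~(D0 | HP);
      VN[w] = HP & D0;
      bscore[w] += hout;
      hin = hout;
    }
    if (last == W - 1 && bscore[W - 1] - (n - 1 - j) > limit) return -1;
  }
  if (last < W - 1) return -1;
  return bscore[W - 1] <= limit ? bscore[W - 1] : -1;
}

// Ukkonen banded edit distance with early exit; returns -1 when > limit.
// Cheaper than the bit-parallel scan for clearly-distant pairs because the
// band fills past the limit early.
static long long banded_ed(const std::string& a, const std::string& b,
                           long long limit) {
  const long long m = (long long)a.size(), n = (long long)b.size();
  if (std::llabs(m - n) > limit) return -1;
  if (m == 0) return n;
  if (n == 0) return m;
  const long long band = limit;
  const long long lo = -band, hi = band; // j - i in [lo, hi]
  const long long width = hi - lo + 1;
  const long long INF = 1LL << 40;
  std::vector<long long> prev(width, INF), cur(width, INF);
  for (long long j = 0; j <= n && j <= hi; ++j) prev[j - lo] = j;
  for (long long i = 1; i <= m; ++i) {
    long long rowmin = INF;
    const long long jmin = std::max((long long)0, i + lo);
    const long long jmax = std::min(n, i + hi);
    if (jmin > jmax) return -1;
    std::fill(cur.begin(), cur.end(), INF);
    for (long long j = jmin; j <= jmax; ++j) {
      const long long off = j - i - lo;
      long long best = INF;
      if (j > 0 && off > 0 && cur[off - 1] + 1 < best) best = cur[off - 1] + 1;
      if (off + 1 < width && prev[off + 1] + 1 < best) best = prev[off + 1] + 1;
      if (j > 0) {
        long long v = prev[off] + (a[i - 1] == b[j - 1] &&
                                   base_code(a[i - 1]) < 4 ? 0 : 1);
        if (v < best) best = v;
      } else if (i < best) best = i;
      cur[off] = best;
      if (best < rowmin) rowmin = best;
    }
    if (rowmin > limit) return -1;
    std::swap(prev, cur);
  }
  const long long d = prev[n - m - lo];
  return d > limit ? -1 : d;
}

// [[Rcpp::export]]
double cpp_edit_distance(std::string a, std::string b, double limit = -1) {
  long long d = (limit < 0) ? myers_ed(a, b, -1)
                            : myers_banded(a, b, (long long)limit);
  return d < 0 ? NA_REAL : (double)d;
}

// Banded global alignment with traceback. band is the half-width added on
// both sides of the corridor spanned by the end-diagonal. Returns the edit
// distance and an operation string over alignment columns:
// M match, X mismatch, D base in a / gap in b, I gap in a / base in b.
// If the optimum leaves the band the reported distance is an upper bound;
// callers size the band from a prior bit-parallel distance so this does not
// happen in practice.
// [[Rcpp::export]]
List cpp_align_global(std::string a, std::string b, int band) {
  const int m = (int)a.size(), n = (int)b.size();
  const int lo = std::min(0, n - m) - band;      // j - i >= lo
  const int hi = std::max(0, n - m) + band;      // j - i <= hi
  const int width = hi - lo + 1;
  const int INF = 1 << 28;
  // score rows (i over a), banded in j
  std::vector<int> prev(width, INF), cur(width, INF);
  std::vector<uint8_t> tb((size_t)(m + 1) * width, 0); // 1=diag 2=up(D) 3=left(I)
  for (int j = 0; j <= n && j - 0 <= hi; ++j) {
    if (j - 0 >= lo) { prev[j - lo] = j; tb[(size_t)0 * width + (j - lo)] = 3; }
  }
  for (int i = 1; i <= m; ++i) {
    std::fill(cur.begin(), cur.end(), INF);
    const int jmin = std::max(0, i + lo), jmax = std::min(n, i + hi);
    for (int j = jmin; j <= jmax; ++j) {
      const int off = j - i - lo;
      int best = INF; uint8_t op = 0;
      if (j > 0 && j - 1 - i >= lo) { // I: gap in a
        int v = cur[off - 1] + 1;
        if (v < best) { best = v; op = 3; }
      }
      if (j - (i - 1) <= hi) {        // D: gap in b
        int v = prev[off + 1] + 1;
        if (v < best) { best = v; op = 2; }
      }
      if (j > 0) {                    // diagonal
        int v = prev[off] + (a[i - 1] == b[j - 1] &&
                             base_code(a[i - 1]) < 4 ? 0 : 1);
        if (v < best) { best = v; op = 1; }
      } else if (i > 0) {             // first column
        int v = i;
        if (v < best) { best = v; op = 2; }
      }
      cur[off] = best; tb[(size_t)i * width + off] = op;
    }
    std::swap(prev, cur);
  }
  const int endOff = n - m - lo;
  if (endOff < 0 || endOff >= width || prev[endOff] >= INF)
    stop("alignment band too narrow");
  const int dist = prev[endOff];
  // traceback
  std::string ops;
  ops.reserve(m + n);
  int i = m, j = n;
  while (i > 0 || j > 0) {
    uint8_t op = tb[(size_t)i * width + (j - i - lo)];
    if (op == 1) {
      ops.push_back(a[i - 1] == b[j - 1] && base_code(a[i - 1]) < 4 ? 'M' : 'X');
      --i; --j;
    } else if (op == 2) { ops.push_back('D'); --i; }
    else if (op == 3) { ops.push_back('I'); --j; }
    else stop("traceback failure");
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(_["dist"] = dist, _["ops"] = ops);
}

// sorted unique 15-mer codes of a sequence (forward strand)
static std::vector<uint32_t> sketch15(const std::string& s) {
  std::vector<uint32_t> v;
  const int k = 15;
  if ((int)s.size() < k) return v;
  uint32_t code = 0, mask = (1u << 30) - 1;
  int run = 0;
  for (size_t i = 0; i < s.size(); ++i) {
    int c = base_code(s[i]);
    if (c >= 4) { run = 0; code = 0; continue; }
    code = ((code << 2) | (uint32_t)c) & mask;
    if (++run >= k) v.push_back(code);
  }
  std::sort(v.begin(), v.end());
  v.erase(std::unique(v.begin(), v.end()), v.end());
  return v;
}

static double shared_frac(const std::vector<uint32_t>& x,
                          const std::vector<uint32_t>& y) {
  if (x.empty() || y.empty()) return 0.0;
  size_t i = 0, j = 0, shared = 0;
  while (i < x.size() && j < y.size()) {
    if (x[i] == y[j]) { ++shared; ++i; ++j; }
    else if (x[i] < y[j]) ++i;
    else ++j;
  }
  return (double)shared / (double)std::min(x.size(), y.size());
}

// All-vs-all threshold-limited edit distances. Entries above the limit (or
// failing the 15-mer sketch prefilter) are NA. A triangle-inequality prune
// over greedily chosen representatives skips pairs that provably exceed the
// limit: with d(i,ri) <= r and d(j,rj) <= r,
// d(i,j) >= d(ri,rj) - d(i,ri) - d(j,rj), so pairs whose representatives
// are far apart never reach the alignment kernel. The result is exact.
// [[Rcpp::export]]
NumericMatrix cpp_pairwise_dist(CharacterVector seqs, double limit,
                                double sketch_min_frac = 0.05) {
  const int n = seqs.size();
  const long long lim = (long long)limit;
  std::vector<std::string> ss(n);
  std::vector<std::vector<uint32_t> > sk(n);
  for (int i = 0; i < n; ++i) {
    ss[i] = as<std::string>(seqs[i]);
    sk[i] = sketch15(ss[i]);
  }
  // greedy representative assignment (radius r)
  const long long r = std::max((long long)20, lim / 4);
  std::vector<int> rep(n, -1);       // representative index per sequence
  std::vector<long long> drep(n, 0); // distance to representative
  std::vector<int> reps;
  for (int i = 0; i < n; ++i) {
    for (size_t t = 0; t < reps.size(); ++t) {
      long long d = myers_banded(ss[i], ss[reps[t]], r);
      if (d >= 0) { rep[i] = reps[t]; drep[i] = d; break; }
    }
    if (rep[i] < 0) { rep[i] = i; drep[i] = 0; reps.push_back(i); }
    if (i % 16 == 0) Rcpp::checkUserInterrupt();
  }
  // representative-level distances up to limit + 2r
  std::map<std::pair<int, int>, long long> repd;
  for (size_t a = 0; a < reps.size(); ++a) {
    for (size_t b = a + 1; b < reps.size(); ++b) {
      long long d = myers_banded(ss[reps[a]], ss[reps[b]], lim + 2 * r);
      repd[std::make_pair(reps[a], reps[b])] = d; // -1 = exceeds
    }
    Rcpp::checkUserInterrupt();
  }
  NumericMatrix D(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) D(i, j) = (i == j) ? 0.0 : NA_REAL;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (rep[i] != rep[j]) {
        int a = std::min(rep[i], rep[j]), b = std::max(rep[i], rep[j]);
        long long dr = repd[std::make_pair(a, b)];
        // representatives further apart than limit + d(i,ri) + d(j,rj)
        // prove d(i,j) > limit
        if (dr < 0 || dr - drep[i] - drep[j] > lim) continue;
      }
      // sketch prefilter (skipped for sequences too short to sketch)
      if (!sk[i].empty() && !sk[j].empty() &&
          shared_frac(sk[i], sk[j]) < sketch_min_frac) continue;
      long long d = myers_banded(ss[i], ss[j], lim);
      if (d >= 0) { D(i, j) = (double)d; D(j, i) = (double)d; }
    }
    if (i % 32 == 0) Rcpp::checkUserInterrupt();
  }
  return D;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (int i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::string r(s.size(), 'N');
    for (size_t j = 0; j < s.size(); ++j) {
      char c = s[s.size() - 1 - j];
      switch (c) {
      case 'A': r[j] = 'T'; break; case 'C': r[j] = 'G'; break;
      case 'G': r[j] = 'C'; break; case 'T': r[j] = 'A'; break;
      default:  r[j] = 'N';
      }
    }
    out[i] = r;
  }
  return out;
}
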