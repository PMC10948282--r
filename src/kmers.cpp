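// Canonical k-mer extraction and read-vs-index matching.
// Canonical form of a k-mer is the lexicographic minimum of the k-mer and
// its reverse complement; windows containing N are skipped.

#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>
#include <unordered_set>
using namespace Rcpp;

static inline char comp(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G';
  case 'G': return 'C'; case 'T': return 'A';
  default: return 'N';
  }
}

static std::string revcomp_str(const std::string& s) {
  std::string r(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i) r[i] = comp(s[s.size() - 1 - i]);
  return r;
}

static inline bool valid_base(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

// emit canonical k-mers of s into out (with multiplicity)
static void canon_kmers(const std::string& s, int k,
                        std::vector<std::string>& out) {
  if ((int)s.size() < k) return;
  int run = 0;
  for (size_t i = 0; i < s.size(); ++i) {
    if (valid_base(s[i])) ++run; else run = 0;
    if (run >= k) {
      std::string f = s.substr(i - k + 1, k);
      std::string r = revcomp_str(f);
      out.push_back(f <= r ? f : r);
    }
  }
}

// Canonical k-mers of a set of sequences with multiplicities, sorted.
// [[Rcpp::export]]
List cpp_count_kmers(CharacterVector seqs, int k) {
  std::vector<std::string> all;
  for (int i = 0; i < seqs.size(); ++i)
    canon_kmers(as<std::string>(seqs[i]), k, all);
  std::sort(all.begin(), all.end());
  std::vector<std::string> uniq;
  std::vector<int> cnt;
  for (size_t i = 0; i < all.size();) {
    size_t j = i;
    while (j < all.size() && all[j] == all[i]) ++j;
    uniq.push_back(all[i]);
    cnt.push_back((int)(j - i));
    i = j;
  }
  return List::create(_["kmer"] = wrap(uniq), _["count"] = wrap(cnt));
}

// Fraction of each read's canonical k-mers present in the index.
// Reads shorter than k (or with no N-free window) get fraction 0.
// [[Rcpp::export]]
NumericVector cpp_match_fraction(CharacterVector reads,
                                 CharacterVector index_kmers, int k) {
  std::unordered_set<std::string> idx;
  idx.reserve(index_kmers.size() * 2);
  for (int i = 0; i < index_kmers.size(); ++i)
    idx.insert(as<std::string>(index_kmers[i]));
  NumericVector out(reads.size());
  for (int i = 0; i < reads.size(); ++i) {
    std::vector<std::string> km;
    canon_kmers(as<std::string>(reads[i]), k, km);
    if (km.empty()) { out[i] = 0.0; continue; }
    size_t hit = 0;
    for (size_t j = 0; j < km.size(); ++j)
      if (idx.count(km[j])) ++hit;
    out[i] = (double)hit / (double)km.size();
    if (i % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Homopolymer compression: collapse runs of identical bases, return the
// compressed strings and per-position run lengths.
// [[Rcpp::export]]
List cpp_hpc_compress(CharacterVector seqs) {
  List comp_out(seqs.size()), runs_out(seqs.size());
  for (int i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::string c;
    std::vector<int> runs;
    for (size_t j = 0; j < s.size(); ++j) {
      if (!c.empty() && s[j] == c[c.size() - 1]) ++runs.back();
      else { c.push_back(s[j]); runs.push_back(1); }
    }
    comp_out[i] = c;
    runs_out[i] = wrap(runs);
  }
  return List::create(_["compressed"] = comp_out, _["runs"] = runs_out);
}

// Expand a homopolymer-compressed string with per-position run lengths.
// [[Rcpp::export]]
std::string cpp_hpc_expand(std::string compressed, IntegerVector runs) {
  if ((int)compressed.size() != runs.size())
    stop("runs length must equal compressed length");
  std::string out;
  size_t total = 0;
  for (int i = 0; i < runs.size(); ++i) total += std::max(1, (int)runs[i]);
  out.reserve(total);
  for (int i = 0; i < runs.size(); ++i)
    out.append(std::max(1, (int)runs[i]), compressed[i]);
  return out;
}
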