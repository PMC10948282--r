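// Sequencing-error injection for the read simulator. Uses R's RNG stream
// (unif_rand) so results are reproducible under set.seed(). Draw order:
// one uniform per template position for the event type, then one extra
// uniform per substituted or (non-homopolymer) inserted base.

#include <Rcpp.h>
#include <string>
using namespace Rcpp;

static const char BASES[4] = {'A', 'C', 'G', 'T'};

// run length of the homopolymer containing position i
static int run_at(const std::string& s, size_t i) {
  char c = s[i];
  int r = 1;
  for (size_t j = i; j > 0 && s[j - 1] == c; --j) ++r;
  for (size_t j = i + 1; j < s.size() && s[j] == c; ++j) ++r;
  return r;
}

// [[Rcpp::export]]
std::string cpp_inject_errors(std::string seq, double sub_rate,
                              double ins_rate, double del_rate,
                              double hp_weight) {
  std::string out;
  out.reserve(seq.size() + (size_t)(seq.size() * ins_rate * 2) + 16);
  for (size_t i = 0; i < seq.size(); ++i) {
    const bool in_hp = run_at(seq, i) >= 3;
    const double w = in_hp ? hp_weight : 1.0;
    const double pd = del_rate * w, pi = ins_rate * w, ps = sub_rate;
    const double u = unif_rand();
    if (u < pd) continue; // deletion
    if (u < pd + pi) {    // insertion before this base
      if (in_hp) out.push_back(seq[i]); // homopolymer expansion
      else out.push_back(BASES[(int)(unif_rand() * 4) & 3]);
      out.push_back(seq[i]);
      continue;
    }
    if (u < pd + pi + ps) { // substitution
      int c;
      switch (seq[i]) {
      case 'A': c = 0; break; case 'C': c = 1; break;
      case 'G': c = 2; break; case 'T': c = 3; break;
      default: c = -1;
      }
      if (c < 0) { out.push_back(seq[i]); continue; }
      int r = 1 + ((int)(unif_rand() * 3) % 3); // offset 1..3 from original
      out.push_back(BASES[(c + r) & 3]);
      continue;
    }
    out.push_back(seq[i]);
  }
  return out;
}
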