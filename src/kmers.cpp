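#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <string>
#include <vector>
using namespace Rcpp;

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) {
    switch (r[i]) {
      case 'A': r[i] = 'T'; break;
      case 'C': r[i] = 'G'; break;
      case 'G': r[i] = 'C'; break;
      case 'T': r[i] = 'A'; break;
      default:  r[i] = 'N';
    }
  }
  return r;
}

// Fraction of a read's distinct k-mers contained in each transcript's
// k-mer set, taking the better of the forward and reverse-complement
// orientation per read. Returns, per read pair, the indices (1-based) of
// transcripts for which BOTH mates reach containment >= tau.
// [[Rcpp::export(name = ".kmer_compat_cpp")]]
List kmer_compat_cpp(CharacterVector mate1, CharacterVector mate2,
                     CharacterVector transcripts, int k, double tau) {
  const int nt = transcripts.size();
  std::unordered_map<std::string, std::vector<int> > index;
  for (int t = 0; t < nt; ++t) {
    std::string seq = as<std::string>(transcripts[t]);
    if ((int)seq.size() < k) continue;
    std::unordered_set<std::string> seen;
    for (size_t p = 0; p + k <= seq.size(); ++p) {
      std::string km = seq.substr(p, k);
      if (seen.insert(km).second) index[km].push_back(t);
    }
  }
  const int nr = mate1.size();
  List out(nr);
  std::vector<int> cnt(nt), touched;
  for (int r = 0; r < nr; ++r) {
    std::vector<double> frac_ok[2];
    for (int mate = 0; mate < 2; ++mate) {
      std::string seq = as<std::string>(mate == 0 ? mate1[r] : mate2[r]);
      double best_frac[2]; // per orientation handled below
      std::vector<double> frac(nt, 0.0);
      for (int ori = 0; ori < 2; ++ori) {
        std::string s = ori == 0 ? seq : revcomp(seq);
        std::unordered_set<std::string> kms;
        for (size_t p = 0; p + k <= s.size(); ++p) kms.insert(s.substr(p, k));
        if (kms.empty()) continue;
        touched.clear();
        for (std::unordered_set<std::string>::const_iterator it = kms.begin();
             it != kms.end(); ++it) {
          std::unordered_map<std::string, std::vector<int> >::const_iterator hit =
            index.find(*it);
          if (hit == index.end()) continue;
          for (size_t z = 0; z < hit->second.size(); ++z) {
            int t = hit->second[z];
            if (cnt[t] == 0) touched.push_back(t);
            ++cnt[t];
          }
        }
        for (size_t z = 0; z < touched.size(); ++z) {
          int t = touched[z];
          double f = (double)cnt[t] / (double)kms.size();
          if (f > frac[t]) frac[t] = f;
          cnt[t] = 0;
        }
      }
      (void)best_frac;
      frac_ok[mate] = frac;
    }
    std::vector<int> compat;
    for (int t = 0; t < nt; ++t)
      if (frac_ok[0][t] >= tau && frac_ok[1][t] >= tau) compat.push_back(t + 1);
    out[r] = wrap(compat);
  }
  return out;
}
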