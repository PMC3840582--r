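#include <Rcpp.h>
#include <string>
using namespace Rcpp;

// Hot loops of the read-quality filter.

// Number of bases below two Phred thresholds per read (Phred+33 strings).
// [[Rcpp::export]]
IntegerMatrix qual_counts_cpp(CharacterVector quals, int q1, int q2) {
  const int n = quals.size();
  IntegerMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    const char *s = CHAR(STRING_ELT(quals, i));
    int a = 0, b = 0;
    for (; *s; ++s) {
      int q = (int)(*s) - 33;
      if (q < q1) ++a;
      if (q < q2) ++b;
    }
    out(i, 0) = a;
    out(i, 1) = b;
  }
  return out;
}

// Earliest position where a prefix of the 3' adapter matches through the
// read end with at most max_mm mismatches and an overlap of >= min_overlap.
// Returns the 0-based adapter start (== insert length), or -1.
// [[Rcpp::export]]
IntegerVector adapter_pos_cpp(CharacterVector seqs, std::string adapter,
                              int min_overlap, int max_mm) {
  const int n = seqs.size();
  const int la = (int)adapter.size();
  IntegerVector out(n, -1);
  for (int i = 0; i < n; ++i) {
    const std::string s = as<std::string>(CharacterVector::create(seqs[i])[0]);
    const int ls = (int)s.size();
    for (int start = 0; start <= ls - min_overlap; ++start) {
      int ov = std::min(la, ls - start);
      if (ov < min_overlap) break;
      int mm = 0;
      for (int k = 0; k < ov && mm <= max_mm; ++k)
        if (s[start + k] != adapter[k]) ++mm;
      if (mm <= max_mm) { out[i] = start; break; }
    }
  }
  return out;
}
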