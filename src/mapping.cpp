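#include <Rcpp.h>
#include <unordered_map>
#include <set>
#include <string>
#include <vector>
using namespace Rcpp;

// Exact-seed-and-extend read mapping (substitutions only, both strands).
// An 8-mer index of the references is probed with tag seeds at offsets 0 and
// 8; with at most one allowed mismatch the pigeonhole principle guarantees
// one of the two seeds is exact for any tag of >= 16 nt.

static inline int bcode(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1; case 'G': return 2;
    case 'U': case 'T': return 3; default: return -1;
  }
}

static inline long kcode(const std::string &s, int pos, int k) {
  long code = 0;
  for (int i = 0; i < k; ++i) {
    int b = bcode(s[pos + i]);
    if (b < 0) return -1;
    code = (code << 2) | b;
  }
  return code;
}

static std::string revcomp_str(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) {
    switch (r[i]) {
      case 'A': r[i] = 'U'; break;
      case 'C': r[i] = 'G'; break;
      case 'G': r[i] = 'C'; break;
      case 'U': case 'T': r[i] = 'A'; break;
      default: break;
    }
  }
  return r;
}

// [[Rcpp::export]]
DataFrame map_tags_cpp(CharacterVector tags, CharacterVector refs,
                       int max_mm) {
  const int K = 8;
  const int nr = refs.size(), nt = tags.size();
  std::vector<std::string> R(nr);
  std::unordered_map<long, std::vector<std::pair<int, int> > > idx;
  for (int r = 0; r < nr; ++r) {
    R[r] = as<std::string>(refs[r]);
    for (int pos = 0; pos + K <= (int)R[r].size(); ++pos) {
      long c = kcode(R[r], pos, K);
      if (c >= 0) idx[c].push_back(std::make_pair(r, pos));
    }
  }
  std::vector<int> o_tag, o_ref, o_start, o_end, o_edits;
  std::vector<std::string> o_strand;
  for (int t = 0; t < nt; ++t) {
    std::string fwd = as<std::string>(tags[t]);
    const int L = (int)fwd.size();
    if (L < K) continue;
    for (int sdir = 0; sdir < 2; ++sdir) {
      std::string q = sdir == 0 ? fwd : revcomp_str(fwd);
      std::set<std::pair<int, int> > seen;  // (ref, start)
      std::vector<int> offs;
      offs.push_back(0);
      if (max_mm > 0 && L >= 2 * K) offs.push_back(K);
      for (size_t oi = 0; oi < offs.size(); ++oi) {
        long c = kcode(q, offs[oi], K);
        if (c < 0) continue;
        std::unordered_map<long, std::vector<std::pair<int, int> > >::iterator
            it = idx.find(c);
        if (it == idx.end()) continue;
        for (size_t h = 0; h < it->second.size(); ++h) {
          int r = it->second[h].first;
          int start = it->second[h].second - offs[oi];
          if (start < 0 || start + L > (int)R[r].size()) continue;
          if (seen.count(std::make_pair(r, start))) continue;
          int mm = 0;
          const std::string &ref = R[r];
          for (int i = 0; i < L && mm <= max_mm; ++i) {
            char a = q[i], b = ref[start + i];
            if (a == 'T') a = 'U';
            if (b == 'T') b = 'U';
            if (a != b) ++mm;
          }
          if (mm > max_mm) continue;
          seen.insert(std::make_pair(r, start));
          o_tag.push_back(t + 1); o_ref.push_back(r + 1);
          o_start.push_back(start); o_end.push_back(start + L);
          o_strand.push_back(sdir == 0 ? "+" : "-");
          o_edits.push_back(mm);
        }
      }
    }
  }
  return DataFrame::create(
      _["tag"] = o_tag, _["ref"] = o_ref, _["start"] = o_start,
      _["end"] = o_end, _["strand"] = o_strand, _["edits"] = o_edits,
      _["stringsAsFactors"] = false);
}
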