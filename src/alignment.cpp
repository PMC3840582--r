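#include <Rcpp.h>
#include <unordered_map>
#include <set>
#include <string>
#include <vector>
#include <climits>
using namespace Rcpp;

// Edit-bounded semiglobal alignment: the tag is consumed end-to-end, the
// reference end points are free, every edit (mismatch or 1-nt gap) costs 1.
// Replaces the BlastN searches of the original protocol with a deterministic,
// strictly more sensitive bounded matcher for 18-30 nt queries.

struct Aln {
  bool found = false;
  int mismatches = 0, gaps = 0, seed_viol = 0;
  int ref_start = 0, ref_end = 0;   // 0-based half-open on the reference
  std::string atag, aref;
  int edits() const { return mismatches + gaps; }
};

// Full dynamic program over tag (rows) x ref (cols); free first row (start
// anywhere in ref), minimum over last row (end anywhere).  Traceback
// preference diagonal > tag-gap-in-ref > ref-gap-in-tag for determinism.
static Aln dp_align(const std::string &tag, const std::string &ref,
                    int max_edits, int seed_lo, int seed_hi) {
  Aln out;
  const int m = (int)tag.size(), n = (int)ref.size();
  if (m == 0) return out;
  std::vector<int> D((m + 1) * (n + 1));
  auto at = [&](int i, int j) -> int & { return D[i * (n + 1) + j]; };
  for (int j = 0; j <= n; ++j) at(0, j) = 0;
  for (int i = 1; i <= m; ++i) {
    at(i, 0) = i;
    for (int j = 1; j <= n; ++j) {
      int diag = at(i - 1, j - 1) + (tag[i - 1] == ref[j - 1] ? 0 : 1);
      int up = at(i - 1, j) + 1;    // tag base against gap
      int left = at(i, j - 1) + 1;  // ref base skipped
      at(i, j) = std::min(diag, std::min(up, left));
    }
  }
  int best = INT_MAX, jend = -1;
  for (int j = 0; j <= n; ++j)
    if (at(m, j) < best) { best = at(m, j); jend = j; }
  if (best > max_edits) return out;
  // traceback
  int i = m, j = jend;
  std::string atag, aref;
  while (i > 0) {
    if (j > 0 && at(i, j) == at(i - 1, j - 1) + (tag[i - 1] == ref[j - 1] ? 0 : 1)) {
      bool mm = tag[i - 1] != ref[j - 1];
      if (mm) {
        ++out.mismatches;
        if (seed_lo > 0 && i >= seed_lo && i <= seed_hi) ++out.seed_viol;
      }
      atag.push_back(tag[i - 1]); aref.push_back(ref[j - 1]);
      --i; --j;
    } else if (at(i, j) == at(i - 1, j) + 1) {
      ++out.gaps;
      if (seed_lo > 0 && i >= seed_lo && i <= seed_hi) ++out.seed_viol;
      atag.push_back(tag[i - 1]); aref.push_back('-');
      --i;
    } else {
      ++out.gaps;
      // a gap between tag positions i and i+1 counts against the seed when
      // the next consumed tag base lies inside it
      if (seed_lo > 0 && (i + 1) >= seed_lo && (i + 1) <= seed_hi) ++out.seed_viol;
      atag.push_back('-'); aref.push_back(ref[j - 1]);
      --j;
    }
  }
  out.found = true;
  out.ref_start = j;
  out.ref_end = jend;
  std::reverse(atag.begin(), atag.end());
  std::reverse(aref.begin(), aref.end());
  out.atag = atag; out.aref = aref;
  return out;
}

// [[Rcpp::export]]
List align_tag_cpp(std::string tag, std::string ref, int max_edits,
                   int seed_lo, int seed_hi) {
  Aln a = dp_align(tag, ref, max_edits, seed_lo, seed_hi);
  return List::create(
      _["found"] = a.found, _["mismatches"] = a.mismatches, _["gaps"] = a.gaps,
      _["seed_violations"] = a.seed_viol, _["ref_start"] = a.ref_start,
      _["ref_end"] = a.ref_end, _["aligned_tag"] = a.atag,
      _["aligned_ref"] = a.aref);
}

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1; case 'G': return 2;
    case 'U': case 'T': return 3; default: return -1;
  }
}

static inline long kmer_code(const std::string &s, int pos, int k) {
  long code = 0;
  for (int i = 0; i < k; ++i) {
    int b = base_code(s[pos + i]);
    if (b < 0) return -1;
    code = (code << 2) | b;
  }
  return code;
}

// Best bounded match of every tag against a reference set.  Pigeonhole
// k-mer seeding: an alignment with <= e edits must contain one exact piece of
// length floor(|tag|/(e+1)) at a known tag offset, so only seeded reference
// windows are aligned.  Ties break to fewest seed violations, then the
// earlier reference (callers pass references sorted by id), then the
// leftmost hit.
// [[Rcpp::export]]
List match_refset_cpp(CharacterVector tags, CharacterVector refs,
                      int max_edits, bool protect_seed, int seed_lo,
                      int seed_hi, int max_len_diff) {
  const int nt = tags.size(), nr = refs.size();
  std::vector<std::string> R(nr);
  for (int r = 0; r < nr; ++r) R[r] = as<std::string>(refs[r]);
  int p = 18 / (max_edits + 1);
  if (p > 12) p = 12;
  if (p < 4) p = 4;
  std::unordered_map<long, std::vector<std::pair<int, int> > > idx;
  for (int r = 0; r < nr; ++r) {
    const std::string &s = R[r];
    for (int pos = 0; pos + p <= (int)s.size(); ++pos) {
      long c = kmer_code(s, pos, p);
      if (c >= 0) idx[c].push_back(std::make_pair(r, pos));
    }
  }
  IntegerVector o_ref(nt, NA_INTEGER), o_mm(nt, NA_INTEGER),
      o_gap(nt, NA_INTEGER), o_sv(nt, NA_INTEGER), o_rs(nt, NA_INTEGER),
      o_re(nt, NA_INTEGER);
  CharacterVector o_at(nt, NA_STRING), o_ar(nt, NA_STRING);
  const int slo = protect_seed ? seed_lo : 0;
  const int shi = protect_seed ? seed_hi : 0;
  for (int t = 0; t < nt; ++t) {
    std::string tag = as<std::string>(tags[t]);
    const int L = (int)tag.size();
    int piece = L / (max_edits + 1);
    if (piece < p) continue;  // too short for seeding; QC guarantees >= 18
    std::set<std::pair<int, int> > cand;  // (ref, window start)
    for (int k = 0; k <= max_edits; ++k) {
      int off = k * piece;
      long c = kmer_code(tag, off, p);
      if (c < 0) continue;
      std::unordered_map<long, std::vector<std::pair<int, int> > >::iterator it =
          idx.find(c);
      if (it == idx.end()) continue;
      for (size_t h = 0; h < it->second.size(); ++h) {
        int r = it->second[h].first, pos = it->second[h].second;
        if (max_len_diff >= 0 &&
            std::abs((int)R[r].size() - L) > max_len_diff)
          continue;
        int ws = pos - off - max_edits;
        if (ws < 0) ws = 0;
        cand.insert(std::make_pair(r, ws));
      }
    }
    Aln best;
    int best_ref = -1;
    for (std::set<std::pair<int, int> >::iterator it = cand.begin();
         it != cand.end(); ++it) {
      int r = it->first, ws = it->second;
      int we = ws + L + 2 * max_edits + 1;
      if (we > (int)R[r].size()) we = (int)R[r].size();
      if (we - ws < L - max_edits) continue;
      Aln a = dp_align(tag, R[r].substr(ws, we - ws), max_edits, slo, shi);
      if (!a.found) continue;
      if (protect_seed && a.seed_viol > 0) continue;
      a.ref_start += ws; a.ref_end += ws;
      bool better =
          best_ref < 0 || a.edits() < best.edits() ||
          (a.edits() == best.edits() &&
           (a.seed_viol < best.seed_viol ||
            (a.seed_viol == best.seed_viol &&
             (r < best_ref || (r == best_ref && a.ref_start < best.ref_start)))));
      if (better) { best = a; best_ref = r; }
    }
    if (best_ref >= 0) {
      o_ref[t] = best_ref + 1;
      o_mm[t] = best.mismatches; o_gap[t] = best.gaps;
      o_sv[t] = best.seed_viol; o_rs[t] = best.ref_start;
      o_re[t] = best.ref_end;
      o_at[t] = best.atag; o_ar[t] = best.aref;
    }
  }
  return List::create(_["ref"] = o_ref, _["mismatches"] = o_mm,
                      _["gaps"] = o_gap, _["seed_violations"] = o_sv,
                      _["ref_start"] = o_rs, _["ref_end"] = o_re,
                      _["aligned_tag"] = o_at, _["aligned_ref"] = o_ar);
}
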