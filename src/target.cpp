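#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Complementarity alignment of a miRNA against a (reversed) target site,
// local with affine gaps and position-dependent weights: columns consuming
// miRNA seed positions (seed_lo..seed_hi, 1-based from the 5' end) are
// scaled by seed_scale.  Column scores: canonical pair +match, G:U +wobble,
// otherwise +mismatch (negative); 'N' masks a target base entirely.

static inline double pair_score(char m, char t, double match, double wobble,
                                double mism, char *sym) {
  if (m == 'T') m = 'U';
  if (t == 'T') t = 'U';
  if (m == 'N' || t == 'N') { *sym = '.'; return -1e6; }
  if ((m == 'A' && t == 'U') || (m == 'U' && t == 'A') ||
      (m == 'G' && t == 'C') || (m == 'C' && t == 'G')) {
    *sym = '|';
    return match;
  }
  if ((m == 'G' && t == 'U') || (m == 'U' && t == 'G')) {
    *sym = ':';
    return wobble;
  }
  *sym = '.';
  return mism;
}

// [[Rcpp::export]]
List target_align_cpp(std::string mir, std::string rtar, double match,
                      double wobble, double mism, double gopen, double gext,
                      int seed_lo, int seed_hi, double seed_scale) {
  const int m = (int)mir.size(), n = (int)rtar.size();
  const double NEG = -1e18;
  std::vector<double> M((m + 1) * (n + 1), NEG), X((m + 1) * (n + 1), NEG),
      Y((m + 1) * (n + 1), NEG);
  std::vector<signed char> tbM((m + 1) * (n + 1), 0),
      tbX((m + 1) * (n + 1), 0), tbY((m + 1) * (n + 1), 0);
  auto ix = [&](int i, int j) { return i * (n + 1) + j; };
  auto w = [&](int i) {
    return (i >= seed_lo && i <= seed_hi) ? seed_scale : 1.0;
  };
  for (int j = 0; j <= n; ++j) M[ix(0, j)] = 0.0;
  for (int i = 0; i <= m; ++i) M[ix(i, 0)] = 0.0;
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      char sym;
      double s = pair_score(mir[i - 1], rtar[j - 1], match, wobble, mism,
                            &sym) * w(i);
      // gap in target (miRNA base unpaired), weight follows the miRNA pos
      double xo = M[ix(i - 1, j)] - gopen * w(i);
      double xe = X[ix(i - 1, j)] - gext * w(i);
      X[ix(i, j)] = std::max(xo, xe);
      tbX[ix(i, j)] = xo >= xe ? 1 : 2;
      // gap in miRNA (target base unpaired), unscaled
      double yo = M[ix(i, j - 1)] - gopen;
      double ye = Y[ix(i, j - 1)] - gext;
      Y[ix(i, j)] = std::max(yo, ye);
      tbY[ix(i, j)] = yo >= ye ? 1 : 2;
      double dM = M[ix(i - 1, j - 1)], dX = X[ix(i - 1, j - 1)],
             dY = Y[ix(i - 1, j - 1)];
      double prev = std::max(dM, std::max(dX, dY));
      double v = prev + s;
      signed char tb = (prev == dM) ? 1 : (prev == dX ? 2 : 3);
      if (v < 0.0) { v = 0.0; tb = 0; }
      M[ix(i, j)] = v;
      tbM[ix(i, j)] = tb;
      if (v > best) { best = v; bi = i; bj = j; }
    }
  }
  std::string am, at, ap;
  int i = bi, j = bj, state = 1;  // 1=M, 2=X, 3=Y
  int mend = bi, tend = bj;
  while (i > 0 && j > 0) {
    if (state == 1) {
      signed char tb = tbM[ix(i, j)];
      if (tb == 0 || M[ix(i, j)] == 0.0) break;
      char sym;
      pair_score(mir[i - 1], rtar[j - 1], match, wobble, mism, &sym);
      am.push_back(mir[i - 1]);
      at.push_back(rtar[j - 1]);
      ap.push_back(sym);
      --i; --j;
      state = tb;
      if (state == 1 && M[ix(i, j)] == 0.0 && tbM[ix(i, j)] == 0) break;
    } else if (state == 2) {
      am.push_back(mir[i - 1]);
      at.push_back('-');
      ap.push_back('-');
      state = tbX[ix(i, j)] == 1 ? 1 : 2;
      --i;
    } else {
      am.push_back('-');
      at.push_back(rtar[j - 1]);
      ap.push_back('-');
      state = tbY[ix(i, j)] == 1 ? 1 : 3;
      --j;
    }
  }
  std::reverse(am.begin(), am.end());
  std::reverse(at.begin(), at.end());
  std::reverse(ap.begin(), ap.end());
  return List::create(_["score"] = best, _["aligned_mirna"] = am,
                      _["aligned_target"] = at, _["pairs"] = ap,
                      _["mir_start"] = i + 1, _["mir_end"] = mend,
                      _["tar_start"] = j, _["tar_end"] = tend);
}
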