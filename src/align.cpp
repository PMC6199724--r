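// Banded end-free global alignment with affine gap costs.
//
// Scoring: match / mismatch per column, affine gaps (first gap character
// costs `gapOpen`, each further character `gapExtend`), terminal gaps in
// either sequence are free and excluded from the identity denominator.
// The band is expressed as the maximum deviation of j - i from the range
// implied by the length difference; band < 0 disables banding (full DP).

#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>

using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// state codes for traceback
enum { ST_M = 0, ST_X = 1, ST_Y = 2 };  // X: gap in b (consume a), Y: gap in a

// [[Rcpp::export(name = ".alignGlobalCpp")]]
List alignGlobalCpp(std::string a, std::string b,
                    double match = 1.0, double mismatch = -2.0,
                    double gapOpen = -4.0, double gapExtend = -1.0,
                    int band = -1) {
  const int n = (int)a.size(), m = (int)b.size();
  if (n == 0 || m == 0) stop("sequences must be non-empty");

  // j ranges over [i + lo, i + hi] for row i
  int lo, hi;
  if (band < 0) { lo = -n; hi = m; }
  else {
    lo = std::min(0, m - n) - band;
    hi = std::max(0, m - n) + band;
  }
  const int w = hi - lo + 1;

  // banded storage: cell (i, j) lives at [i][j - i - lo]
  std::vector<double> M((size_t)(n + 1) * w, NEG_INF),
                      X((size_t)(n + 1) * w, NEG_INF),
                      Y((size_t)(n + 1) * w, NEG_INF);
  std::vector<signed char> tM((size_t)(n + 1) * w, -1),
                           tX((size_t)(n + 1) * w, -1),
                           tY((size_t)(n + 1) * w, -1);

  auto idx = [&](int i, int j) -> long { return (long)i * w + (j - i - lo); };
  auto inBand = [&](int i, int j) -> bool {
    return j >= 0 && j <= m && (j - i) >= lo && (j - i) <= hi;
  };

  // initialisation: leading terminal gaps are free.
  if (inBand(0, 0)) M[idx(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) if (inBand(i, 0)) { X[idx(i, 0)] = 0.0; tX[idx(i, 0)] = ST_X; }
  for (int j = 1; j <= m; ++j) if (inBand(0, j)) { Y[idx(0, j)] = 0.0; tY[idx(0, j)] = ST_Y; }

  for (int i = 1; i <= n; ++i) {
    const int jmin = std::max(1, i + lo), jmax = std::min(m, i + hi);
    for (int j = jmin; j <= jmax; ++j) {
      const long c = idx(i, j);
      // M from diagonal
      if (inBand(i - 1, j - 1)) {
        const long d = idx(i - 1, j - 1);
        double best = M[d]; signed char st = ST_M;
        if (X[d] > best) { best = X[d]; st = ST_X; }
        if (Y[d] > best) { best = Y[d]; st = ST_Y; }
        if (best > NEG_INF) {
          M[c] = best + (a[i - 1] == b[j - 1] ? match : mismatch);
          tM[c] = st;
        }
      }
      // X: a[i-1] aligned to gap (move up)
      if (inBand(i - 1, j)) {
        const long u = idx(i - 1, j);
        double fromM = (M[u] > Y[u] ? M[u] : Y[u]);
        signed char stM = (M[u] >= Y[u] ? ST_M : ST_Y);
        double openv = fromM > NEG_INF ? fromM + gapOpen : NEG_INF;
        double extv  = X[u] > NEG_INF ? X[u] + gapExtend : NEG_INF;
        // free leading gap column kept free while j == 0 handled in init
        if (openv >= extv) { X[c] = openv; tX[c] = stM; }
        else               { X[c] = extv;  tX[c] = ST_X; }
      }
      // Y: b[j-1] aligned to gap (move left)
      if (inBand(i, j - 1)) {
        const long l = idx(i, j - 1);
        double fromM = (M[l] > X[l] ? M[l] : X[l]);
        signed char stM = (M[l] >= X[l] ? ST_M : ST_X);
        double openv = fromM > NEG_INF ? fromM + gapOpen : NEG_INF;
        double extv  = Y[l] > NEG_INF ? Y[l] + gapExtend : NEG_INF;
        if (openv >= extv) { Y[c] = openv; tY[c] = stM; }
        else               { Y[c] = extv;  tY[c] = ST_Y; }
      }
    }
  }

  // termination: trailing terminal gaps free -> best over last row / column,
  // preferring M/X/Y value at each terminal cell.
  double best = NEG_INF; int bi = n, bj = m; signed char bst = ST_M;
  for (int j = 0; j <= m; ++j) {
    if (!inBand(n, j)) continue;
    const long c = idx(n, j);
    if (M[c] > best) { best = M[c]; bi = n; bj = j; bst = ST_M; }
    if (X[c] > best) { best = X[c]; bi = n; bj = j; bst = ST_X; }
    if (Y[c] > best && j == m) { best = Y[c]; bi = n; bj = j; bst = ST_Y; }
  }
  for (int i = 0; i <= n; ++i) {
    if (!inBand(i, m)) continue;
    const long c = idx(i, m);
    if (M[c] > best) { best = M[c]; bi = i; bj = m; bst = ST_M; }
    if (Y[c] > best) { best = Y[c]; bi = i; bj = m; bst = ST_Y; }
  }
  if (best == NEG_INF) stop("band too narrow: no alignment found");

  // traceback of the aligned core
  std::string ca, cb;
  int i = bi, j = bj; signed char st = bst;
  while (i > 0 || j > 0) {
    if (st == ST_M) {
      if (i == 0 || j == 0) break;
      signed char prev = tM[idx(i, j)];
      ca.push_back(a[i - 1]); cb.push_back(b[j - 1]);
      --i; --j; st = prev;
    } else if (st == ST_X) {
      if (j == 0) break;  // leading free gap region
      signed char prev = tX[idx(i, j)];
      ca.push_back(a[i - 1]); cb.push_back('-');
      --i; st = prev;
    } else {
      if (i == 0) break;  // leading free gap region
      signed char prev = tY[idx(i, j)];
      ca.push_back('-'); cb.push_back(b[j - 1]);
      --j; st = prev;
    }
  }
  // i, j now mark the start of the aligned core; the prefix is terminal gaps
  int leadA = i, leadB = j;
  std::reverse(ca.begin(), ca.end());
  std::reverse(cb.begin(), cb.end());

  // assemble full gapped strings with terminal overhangs
  std::string fa, fb;
  for (int k = 0; k < leadA; ++k) { fa.push_back(a[k]); fb.push_back('-'); }
  for (int k = 0; k < leadB; ++k) { fa.push_back('-'); fb.push_back(b[k]); }
  fa += ca; fb += cb;
  for (int k = bi; k < n; ++k) { fa.push_back(a[k]); fb.push_back('-'); }
  for (int k = bj; k < m; ++k) { fa.push_back('-'); fb.push_back(b[k]); }

  // column statistics over the aligned core only
  int matches = 0, mismatches = 0, internalGaps = 0;
  for (size_t k = 0; k < ca.size(); ++k) {
    if (ca[k] == '-' || cb[k] == '-') ++internalGaps;
    else if (ca[k] == cb[k]) ++matches;
    else ++mismatches;
  }
  int termA = leadB + (m - bj);  // gap chars opposite overhangs of b in a
  int termB = leadA + (n - bi);
  int denom = matches + mismatches + internalGaps;
  double identity = denom > 0 ? (double)matches / denom : 0.0;

  return List::create(
    _["aligned_a"] = fa, _["aligned_b"] = fb,
    _["score"] = best,
    _["matches"] = matches, _["mismatches"] = mismatches,
    _["internal_gap_columns"] = internalGaps,
    _["terminal_gap_a"] = termA, _["terminal_gap_b"] = termB,
    _["identity"] = identity);
}
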