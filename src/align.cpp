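#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Affine-gap pairwise aligner over integer-encoded sequences.
//
// Gap convention: a gap of length L costs gap_open + L * gap_extend, with
// gap_open and gap_extend passed as (negative) scores.
//
// States: M = a[i] aligned to b[j]; X = gap in b (consumes a, "up");
//         Y = gap in a (consumes b, "left").
// Traceback tie-break is M > X > Y everywhere, i.e. diagonal > up > left.
//
// Free end gaps are implemented as start/end anywhere on the corresponding
// DP boundary; the skipped flanks are NOT emitted as gap columns but are
// reflected in the returned span coordinates, so the gapped strings never
// contain a column that is gap-over-gap.

static const double NEG = -1e30;
static const uint8_t P_M = 0, P_X = 1, P_Y = 2, P_START = 3;

// [[Rcpp::export(name = ".affine_align_cpp")]]
List affine_align_cpp(IntegerVector a, IntegerVector b, NumericMatrix S,
                      double gap_open, double gap_extend,
                      bool free_a_start, bool free_a_end,
                      bool free_b_start, bool free_b_end) {
  const R_xlen_t n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("empty sequence");
  const double go = gap_open, ge = gap_extend;

  // traceback matrices, one byte per state per cell
  const R_xlen_t ncell = (n + 1) * (m + 1);
  std::vector<uint8_t> pm(ncell), px(ncell), py(ncell);
  // rolling score rows
  std::vector<double> Mprev(m + 1), Xprev(m + 1), Yprev(m + 1);
  std::vector<double> Mcur(m + 1), Xcur(m + 1), Ycur(m + 1);

  auto IDX = [m](R_xlen_t i, R_xlen_t j) { return i * (m + 1) + j; };

  // row i = 0
  Mprev[0] = 0.0; Xprev[0] = NEG; Yprev[0] = NEG;
  pm[IDX(0, 0)] = P_START;
  for (R_xlen_t j = 1; j <= m; ++j) {
    if (free_b_start) {
      Mprev[j] = 0.0; pm[IDX(0, j)] = P_START;
      Yprev[j] = NEG;
    } else {
      Mprev[j] = NEG;
      Yprev[j] = go + j * ge; py[IDX(0, j)] = P_Y;
    }
    Xprev[j] = NEG;
  }

  // best end bookkeeping
  double best = NEG; R_xlen_t bi = n, bj = m; uint8_t bstate = P_M;
  auto consider = [&](double sc, R_xlen_t i, R_xlen_t j, uint8_t st) {
    if (sc > best) { best = sc; bi = i; bj = j; bstate = st; }
  };

  for (R_xlen_t i = 1; i <= n; ++i) {
    // column j = 0
    if (free_a_start) {
      Mcur[0] = 0.0; pm[IDX(i, 0)] = P_START;
      Xcur[0] = NEG;
    } else {
      Mcur[0] = NEG;
      Xcur[0] = go + i * ge; px[IDX(i, 0)] = P_X;
    }
    Ycur[0] = NEG;

    const int ai = a[i - 1];
    for (R_xlen_t j = 1; j <= m; ++j) {
      // M: diagonal from (i-1, j-1); predecessor preference M > X > Y
      double pMM = Mprev[j - 1], pMX = Xprev[j - 1], pMY = Yprev[j - 1];
      double mb = pMM; uint8_t mp = P_M;
      if (pMX > mb) { mb = pMX; mp = P_X; }
      if (pMY > mb) { mb = pMY; mp = P_Y; }
      Mcur[j] = mb + S(ai, b[j - 1]);
      pm[IDX(i, j)] = mp;

      // X: gap in b, from (i-1, j)
      double xM = Mprev[j] + go + ge, xX = Xprev[j] + ge, xY = Yprev[j] + go + ge;
      double xb = xM; uint8_t xp = P_M;
      if (xX > xb) { xb = xX; xp = P_X; }
      if (xY > xb) { xb = xY; xp = P_Y; }
      Xcur[j] = xb; px[IDX(i, j)] = xp;

      // Y: gap in a, from (i, j-1)
      double yM = Mcur[j - 1] + go + ge, yX = Xcur[j - 1] + go + ge, yY = Ycur[j - 1] + ge;
      double yb = yM; uint8_t yp = P_M;
      if (yX > yb) { yb = yX; yp = P_X; }
      if (yY > yb) { yb = yY; yp = P_Y; }
      Ycur[j] = yb; py[IDX(i, j)] = yp;
    }

    // candidate ends along the i = n row (suffix of b unaligned)
    if (i == n && free_b_end) {
      for (R_xlen_t j = m; j >= 1; --j) {
        consider(Mcur[j], n, j, P_M);
        consider(Xcur[j], n, j, P_X);
        consider(Ycur[j], n, j, P_Y);
      }
    }
    // candidate ends along the j = m column (suffix of a unaligned)
    if (free_a_end && i < n) {
      consider(Mcur[m], i, m, P_M);
      consider(Xcur[m], i, m, P_X);
      consider(Ycur[m], i, m, P_Y);
    }

    std::swap(Mprev, Mcur); std::swap(Xprev, Xcur); std::swap(Yprev, Ycur);
  }

  // corner (n, m), preferred on ties (checked last only if strictly better,
  // so check it first by running consider() with >=-style preference):
  // simplest: treat the corner as the default and only switch if a free end
  // strictly improved on it.
  {
    double cM = Mprev[m], cX = Xprev[m], cY = Yprev[m];
    double cb = cM; uint8_t cp = P_M;
    if (cX > cb) { cb = cX; cp = P_X; }
    if (cY > cb) { cb = cY; cp = P_Y; }
    if (!((free_b_end || free_a_end) && best > cb)) {
      best = cb; bi = n; bj = m; bstate = cp;
    }
  }

  if (best <= NEG / 2) stop("alignment infeasible");

  // traceback: walk predecessors until a START cell (the corner (0,0) or a
  // free-start boundary cell) is reached in state M
  std::vector<int> acol, bcol;  // 1-based positions, 0 = gap
  R_xlen_t i = bi, j = bj; uint8_t st = bstate;
  for (;;) {
    if (i == 0 && j == 0) break;
    if (st == P_M && pm[IDX(i, j)] == P_START) break;
    if (st == P_M) {
      uint8_t p = pm[IDX(i, j)];
      acol.push_back((int)i); bcol.push_back((int)j);
      --i; --j; st = p;
    } else if (st == P_X) {
      uint8_t p = px[IDX(i, j)];
      acol.push_back((int)i); bcol.push_back(0);
      --i; st = p;
    } else { // P_Y
      uint8_t p = py[IDX(i, j)];
      acol.push_back(0); bcol.push_back((int)j);
      --j; st = p;
    }
  }

  std::reverse(acol.begin(), acol.end());
  std::reverse(bcol.begin(), bcol.end());

  // span coordinates, 0-based half-open in the ungapped sequences
  R_xlen_t a_start = i, b_start = j, a_end = bi, b_end = bj;

  return List::create(
    _["score"] = best,
    _["a_idx"] = IntegerVector(acol.begin(), acol.end()),
    _["b_idx"] = IntegerVector(bcol.begin(), bcol.end()),
    _["a_start"] = (double)a_start, _["a_end"] = (double)a_end,
    _["b_start"] = (double)b_start, _["b_end"] = (double)b_end);
}
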