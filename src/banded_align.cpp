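#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstdint>
#include <limits>

using namespace Rcpp;

// Banded global alignment with affine gaps (Gotoh). Score model:
// match +1, mismatch -2, a gap of length L costs gap_open + L * gap_extend
// (both negative). 'N' never matches. The band covers diagonals
// d = j - i in [min(0, m-n) - band, max(0, m-n) + band], so the endpoint
// (n, m) is always inside the band. band_hit reports whether the optimal
// traceback touched a band edge, in which case the caller should retry
// with a wider band.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export(name = ".banded_align_cpp")]]
List banded_align_cpp(std::string a, std::string b, int band,
                      double match = 1.0, double mismatch = -2.0,
                      double gap_open = -4.0, double gap_extend = -1.0) {
  const int n = (int)a.size();
  const int m = (int)b.size();
  if (band < 1) stop("band must be >= 1");

  const int dlo = std::min(0, m - n) - band;
  const int dhi = std::max(0, m - n) + band;
  const int W = dhi - dlo + 1;

  // rolling score rows, full traceback (1 byte per cell)
  std::vector<double> Mprev(W, NEG_INF), Xprev(W, NEG_INF), Yprev(W, NEG_INF);
  std::vector<double> Mcur(W, NEG_INF), Xcur(W, NEG_INF), Ycur(W, NEG_INF);
  // tb bits: 0-1 = M source (0 diagM, 1 diagX, 2 diagY),
  //          2 = X source (0 from M, 1 from X), 3 = Y source (0 from M, 1 from Y)
  std::vector<uint8_t> tb((size_t)(n + 1) * W, 0);

  // row 0
  {
    int jlo = std::max(0, dlo), jhi = std::min(m, dhi);
    for (int j = jlo; j <= jhi; ++j) {
      int k = j - 0 - dlo;
      if (j == 0) {
        Mprev[k] = 0.0;
      } else {
        Yprev[k] = gap_open + gap_extend * j;
        if (j > 1) tb[(size_t)0 * W + k] |= 8; // Y from Y
      }
    }
  }

  for (int i = 1; i <= n; ++i) {
    std::fill(Mcur.begin(), Mcur.end(), NEG_INF);
    std::fill(Xcur.begin(), Xcur.end(), NEG_INF);
    std::fill(Ycur.begin(), Ycur.end(), NEG_INF);
    const int jlo = std::max(0, i + dlo), jhi = std::min(m, i + dhi);
    const char ai = a[i - 1];
    uint8_t *tbrow = &tb[(size_t)i * W];
    for (int j = jlo; j <= jhi; ++j) {
      const int k = j - i - dlo;
      uint8_t t = 0;
      if (j == 0) {
        // first column: only a leading gap in b is possible
        double fromM = Mprev[k + 1] + gap_open + gap_extend;
        double fromX = Xprev[k + 1] + gap_extend;
        if (fromX > fromM) { Xcur[k] = fromX; t |= 4; }
        else Xcur[k] = fromM;
        tbrow[k] = t;
        continue;
      }
      // M: diagonal (i-1, j-1) -> same k in previous row
      double sub = (ai == b[j - 1] && ai != 'N') ? match : mismatch;
      double dm = Mprev[k], dx = Xprev[k], dy = Yprev[k];
      double best = dm; uint8_t src = 0;
      if (dx > best) { best = dx; src = 1; }
      if (dy > best) { best = dy; src = 2; }
      if (best > NEG_INF) Mcur[k] = best + sub;
      t |= src;
      // X: vertical (i-1, j) -> k+1 in previous row
      if (k + 1 < W) {
        double fm = Mprev[k + 1] + gap_open + gap_extend;
        double fx = Xprev[k + 1] + gap_extend;
        if (fx > fm) { Xcur[k] = fx; t |= 4; } else Xcur[k] = fm;
      }
      // Y: horizontal (i, j-1) -> k-1 in current row
      if (k - 1 >= 0) {
        double fm = Mcur[k - 1] + gap_open + gap_extend;
        double fy = Ycur[k - 1] + gap_extend;
        if (fy > fm) { Ycur[k] = fy; t |= 8; } else Ycur[k] = fm;
      }
      tbrow[k] = t;
    }
    std::swap(Mprev, Mcur);
    std::swap(Xprev, Xcur);
    std::swap(Yprev, Ycur);
  }

  // terminal cell
  const int kend = m - n - dlo;
  double sM = Mprev[kend], sX = Xprev[kend], sY = Yprev[kend];
  double score = sM; int state = 0;
  if (sX > score) { score = sX; state = 1; }
  if (sY > score) { score = sY; state = 2; }
  if (score == NEG_INF) stop("no alignment within band");

  // traceback
  std::string ops;
  ops.reserve(n + m);
  int i = n, j = m;
  bool band_hit = false;
  while (i > 0 || j > 0) {
    const int k = j - i - dlo;
    if (k <= 0 || k >= W - 1) band_hit = true;
    const uint8_t t = tb[(size_t)i * W + k];
    if (state == 0) {
      // emitted a substitution column for (i, j)
      char c = (a[i - 1] == b[j - 1] && a[i - 1] != 'N') ? 'M' : 'X';
      ops.push_back(c);
      state = t & 3;
      --i; --j;
      if (i == 0 && j == 0) break;
      if (i == 0) state = 2;
      else if (j == 0) state = 1;
    } else if (state == 1) {
      ops.push_back('I'); // consumes a only (gap in b)
      state = (t & 4) ? 1 : 0;
      --i;
      if (i == 0 && j > 0) state = 2;
    } else {
      ops.push_back('D'); // consumes b only (gap in a)
      state = (t & 8) ? 2 : 0;
      --j;
      if (j == 0 && i > 0) state = 1;
    }
  }
  std::reverse(ops.begin(), ops.end());

  // run-length encode
  std::vector<std::string> op_chr;
  std::vector<int> op_len;
  for (size_t p = 0; p < ops.size(); ) {
    size_t q = p;
    while (q < ops.size() && ops[q] == ops[p]) ++q;
    op_chr.push_back(std::string(1, ops[p]));
    op_len.push_back((int)(q - p));
    p = q;
  }

  return List::create(_["score"] = score,
                      _["op"] = op_chr,
                      _["len"] = op_len,
                      _["band_hit"] = band_hit);
}
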