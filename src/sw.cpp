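#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap local alignment (Smith-Waterman).
// Gap cost convention: a gap of length L costs gap_open + (L-1) * gap_extend
// (the opening position itself carries the full gap_open penalty).
// Sequences arrive as 0-based integer indices into the rows/columns of S.

static inline int max3(int a, int b, int c) {
  return std::max(a, std::max(b, c));
}

// [[Rcpp::export]]
int sw_score_c(IntegerVector a, IntegerVector b, IntegerMatrix S,
               int gap_open, int gap_extend) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) return 0;
  const int NEG = INT_MIN / 4;
  std::vector<int> H(m + 1, 0), Ix(m + 1, NEG), Iy(m + 1, NEG);
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    int Hdiag = 0;          // H[i-1][j-1]
    int Hprev = 0;          // H[i-1][j] before overwrite
    int IxDiag = NEG, IyDiag = NEG;
    H[0] = 0;
    int IyRow = NEG;        // Iy[i][j-1]
    for (int j = 1; j <= m; ++j) {
      Hprev = H[j];
      int IxPrev = Ix[j], IyPrevCol = Iy[j];
      int ix = std::max(Hprev - gap_open, Ix[j] - gap_extend);
      int iy = std::max(H[j - 1] - gap_open, IyRow - gap_extend);
      int sub = S(a[i - 1], b[j - 1]);
      int h = max3(Hdiag, IxDiag, IyDiag) + sub;
      if (h < 0) h = 0;
      Hdiag = Hprev; IxDiag = IxPrev; IyDiag = IyPrevCol;
      H[j] = h; Ix[j] = ix; Iy[j] = iy; IyRow = iy;
      if (h > best) best = h;
    }
  }
  return best;
}

// Full DP with traceback; returns score plus 1-based aligned position
// vectors (NA = gap) for the optimal local alignment ending at the
// highest-scoring cell (first such cell in row-major order).
// [[Rcpp::export]]
List sw_align_c(IntegerVector a, IntegerVector b, IntegerMatrix S,
                int gap_open, int gap_extend) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0)
    return List::create(_["score"] = 0,
                        _["a_pos"] = IntegerVector(0),
                        _["b_pos"] = IntegerVector(0));
  const int NEG = INT_MIN / 4;
  // state matrices and traceback pointers (0 = stop, 1 = H-diag, 2 = Ix, 3 = Iy)
  std::vector<int> H((n + 1) * (m + 1), 0), Ix((n + 1) * (m + 1), NEG),
      Iy((n + 1) * (m + 1), NEG);
  std::vector<unsigned char> ptrH((n + 1) * (m + 1), 0),
      ptrIx((n + 1) * (m + 1), 0), ptrIy((n + 1) * (m + 1), 0);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int fromH = H[at(i - 1, j)] - gap_open;
      int fromIx = Ix[at(i - 1, j)] - gap_extend;
      int ix = std::max(fromH, fromIx);
      ptrIx[at(i, j)] = (fromH >= fromIx) ? 1 : 2;
      int fromH2 = H[at(i, j - 1)] - gap_open;
      int fromIy = Iy[at(i, j - 1)] - gap_extend;
      int iy = std::max(fromH2, fromIy);
      ptrIy[at(i, j)] = (fromH2 >= fromIy) ? 1 : 3;
      int sub = S(a[i - 1], b[j - 1]);
      int dH = H[at(i - 1, j - 1)], dIx = Ix[at(i - 1, j - 1)],
          dIy = Iy[at(i - 1, j - 1)];
      int mx = max3(dH, dIx, dIy);
      int h = mx + sub;
      unsigned char p = (mx == dH) ? 1 : (mx == dIx ? 2 : 3);
      if (h <= 0) { h = 0; p = 0; }
      H[at(i, j)] = h; Ix[at(i, j)] = ix; Iy[at(i, j)] = iy;
      ptrH[at(i, j)] = p;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  std::vector<int> apos, bpos;
  if (best > 0) {
    int i = bi, j = bj, state = 1; // start in H (alignments end on a match/mismatch)
    while (i > 0 && j > 0) {
      if (state == 1) {
        if (H[at(i, j)] == 0) break;
        unsigned char p = ptrH[at(i, j)];
        apos.push_back(i); bpos.push_back(j);
        --i; --j;
        if (p == 0) break;
        state = p;
        if (state == 1 && H[at(i, j)] == 0) break;
      } else if (state == 2) {
        apos.push_back(i); bpos.push_back(NA_INTEGER);
        unsigned char p = ptrIx[at(i, j)];
        --i;
        state = p;
      } else {
        apos.push_back(NA_INTEGER); bpos.push_back(j);
        unsigned char p = ptrIy[at(i, j)];
        --j;
        state = p;
      }
    }
    std::reverse(apos.begin(), apos.end());
    std::reverse(bpos.begin(), bpos.end());
  }
  return List::create(_["score"] = best,
                      _["a_pos"] = wrap(apos),
                      _["b_pos"] = wrap(bpos));
}

// All-vs-all local-alignment score matrix for two lists of index vectors.
// [[Rcpp::export]]
IntegerMatrix sw_matrix_c(List A, List B, IntegerMatrix S,
                          int gap_open, int gap_extend) {
  const int nA = A.size(), nB = B.size();
  IntegerMatrix out(nA, nB);
  for (int i = 0; i < nA; ++i) {
    IntegerVector a = A[i];
    for (int j = 0; j < nB; ++j) {
      IntegerVector b = B[j];
      out(i, j) = sw_score_c(a, b, S, gap_open, gap_extend);
    }
  }
  return out;
}
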