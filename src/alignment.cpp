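#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <climits>
using namespace Rcpp;

// Affine-gap alignment kernels shared by the similarity search and the
// progressive aligner. Gap cost convention throughout: a run of L gapped
// columns costs open + L * ext (BLAST-style 11/1 existence/extension).

static const int IMIN = INT_MIN / 4;
static const double DNEG = -1e18;

// Smith-Waterman (Gotoh) score only; rolling rows over raw arrays, used
// for the all-vs-all search. Sequences are 0-based over the scoring
// alphabet; `sub` is the flattened nstate x nstate score matrix.
static int sw_score(const int* a, int la, const int* b, int lb,
                    const int* sub, int nstate, int open, int ext,
                    int* Mp, int* Ixp, int* Iyp, int* M, int* Ix, int* Iy) {
  const int oe = open + ext;
  for (int j = 0; j <= lb; ++j) { Mp[j] = 0; Ixp[j] = IMIN; Iyp[j] = IMIN; }
  int best = 0;
  for (int i = 1; i <= la; ++i) {
    M[0] = 0; Ix[0] = IMIN; Iy[0] = IMIN;
    const int* srow = sub + (size_t)a[i - 1] * nstate;
    for (int j = 1; j <= lb; ++j) {
      int prev = Mp[j - 1];
      if (Ixp[j - 1] > prev) prev = Ixp[j - 1];
      if (Iyp[j - 1] > prev) prev = Iyp[j - 1];
      if (prev < 0) prev = 0;
      int m = srow[b[j - 1]] + prev;
      if (m < 0) m = 0;
      M[j] = m;
      if (m > best) best = m;
      int x1 = (Mp[j] > Iyp[j] ? Mp[j] : Iyp[j]) - oe;
      int x2 = Ixp[j] - ext;
      Ix[j] = x1 > x2 ? x1 : x2;
      int y1 = (M[j - 1] > Ix[j - 1] ? M[j - 1] : Ix[j - 1]) - oe;
      int y2 = Iy[j - 1] - ext;
      Iy[j] = y1 > y2 ? y1 : y2;
    }
    std::swap(M, Mp); std::swap(Ix, Ixp); std::swap(Iy, Iyp);
  }
  return best;
}

// [[Rcpp::export]]
IntegerMatrix cpp_sw_score_matrix(List seqsA, List seqsB, IntegerMatrix sub,
                                  int open, int ext) {
  const int nA = seqsA.size(), nB = seqsB.size(), ns = sub.nrow();
  std::vector<int> subflat((size_t)ns * ns);
  for (int i = 0; i < ns; ++i)
    for (int j = 0; j < ns; ++j) subflat[(size_t)i * ns + j] = sub(i, j);
  std::vector<std::vector<int> > ea(nA), eb(nB);
  size_t maxlb = 0;
  for (int x = 0; x < nA; ++x) {
    IntegerVector v = seqsA[x];
    ea[x].resize(v.size());
    for (int k = 0; k < v.size(); ++k) ea[x][k] = v[k] - 1;
  }
  for (int y = 0; y < nB; ++y) {
    IntegerVector v = seqsB[y];
    eb[y].resize(v.size());
    for (int k = 0; k < v.size(); ++k) eb[y][k] = v[k] - 1;
    if (eb[y].size() + 1 > maxlb) maxlb = eb[y].size() + 1;
  }
  std::vector<int> buf(6 * (maxlb + 1));
  int* Mp = buf.data();
  int* Ixp = Mp + (maxlb + 1);
  int* Iyp = Ixp + (maxlb + 1);
  int* M = Iyp + (maxlb + 1);
  int* Ix = M + (maxlb + 1);
  int* Iy = Ix + (maxlb + 1);
  IntegerMatrix out(nA, nB);
  for (int x = 0; x < nA; ++x) {
    for (int y = 0; y < nB; ++y) {
      out(x, y) = sw_score(ea[x].data(), (int)ea[x].size(),
                           eb[y].data(), (int)eb[y].size(),
                           subflat.data(), ns, open, ext,
                           Mp, Ixp, Iyp, M, Ix, Iy);
    }
  }
  return out;
}

// Full Smith-Waterman with traceback for one pair: returns the optimal
// local alignment as paired 1-based indices (0 = gap) plus the score.
// [[Rcpp::export]]
List cpp_sw_traceback(IntegerVector a, IntegerVector b, IntegerMatrix sub,
                      int open, int ext) {
  const int la = a.size(), lb = b.size();
  // state 0 = M, 1 = Ix (gap in b), 2 = Iy (gap in a)
  std::vector<std::vector<int> > S(3, std::vector<int>((la + 1) * (lb + 1), IMIN));
  std::vector<std::vector<signed char> > P(3, std::vector<signed char>((la + 1) * (lb + 1), -1));
  #define IDX(i, j) ((i) * (lb + 1) + (j))
  for (int j = 0; j <= lb; ++j) S[0][IDX(0, j)] = 0;
  for (int i = 0; i <= la; ++i) S[0][IDX(i, 0)] = 0;
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= la; ++i) {
    const int ai = a[i - 1] - 1;
    for (int j = 1; j <= lb; ++j) {
      const int d = IDX(i - 1, j - 1), u = IDX(i - 1, j), l = IDX(i, j - 1),
                c = IDX(i, j);
      // M
      int pm = S[0][d], px = S[1][d], py = S[2][d];
      int prev = std::max(std::max(pm, px), py);
      int sc = sub(ai, b[j - 1] - 1);
      if (prev <= 0) { S[0][c] = sc; P[0][c] = 3; /* fresh start */ }
      else {
        S[0][c] = sc + prev;
        P[0][c] = (prev == pm) ? 0 : (prev == px ? 1 : 2);
      }
      if (S[0][c] < 0) { S[0][c] = 0; P[0][c] = 3; }
      if (S[0][c] > best) { best = S[0][c]; bi = i; bj = j; }
      // Ix: consume a[i], gap in b
      int fm = S[0][u] - open - ext, fx = S[1][u] - ext, fy = S[2][u] - open - ext;
      S[1][c] = std::max(std::max(fm, fx), fy);
      P[1][c] = (S[1][c] == fm) ? 0 : (S[1][c] == fx ? 1 : 2);
      // Iy: consume b[j], gap in a
      int gm = S[0][l] - open - ext, gx = S[1][l] - open - ext, gy = S[2][l] - ext;
      S[2][c] = std::max(std::max(gm, gx), gy);
      P[2][c] = (S[2][c] == gy) ? 2 : (S[2][c] == gm ? 0 : 1);
    }
  }
  std::vector<int> ia, ib;
  if (best > 0) {
    int i = bi, j = bj, st = 0;
    while (i > 0 && j > 0) {
      if (st == 0) {
        signed char p = P[0][IDX(i, j)];
        ia.push_back(i); ib.push_back(j); --i; --j;
        if (p == 3) break;
        st = p;
      } else if (st == 1) {
        signed char p = P[1][IDX(i, j)];
        ia.push_back(i); ib.push_back(0); --i;
        st = p;
      } else {
        signed char p = P[2][IDX(i, j)];
        ia.push_back(0); ib.push_back(j); --j;
        st = p;
      }
    }
    std::reverse(ia.begin(), ia.end());
    std::reverse(ib.begin(), ib.end());
  }
  #undef IDX
  return List::create(_["score"] = best, _["a_idx"] = wrap(ia),
                      _["b_idx"] = wrap(ib));
}

// Global (Needleman-Wunsch) affine-gap path over a precomputed
// column-vs-column score matrix (profiles already folded in by the caller).
// Returns total score and the merge path: 1 = both advance, 2 = A column
// against gap, 3 = B column against gap.
// [[Rcpp::export]]
List cpp_nw_path(NumericMatrix colScore, double open, double ext) {
  const int la = colScore.nrow(), lb = colScore.ncol();
  std::vector<std::vector<double> > S(3, std::vector<double>((la + 1) * (lb + 1), DNEG));
  std::vector<std::vector<signed char> > P(3, std::vector<signed char>((la + 1) * (lb + 1), -1));
  #define IDX(i, j) ((i) * (lb + 1) + (j))
  S[0][IDX(0, 0)] = 0.0;
  for (int i = 1; i <= la; ++i) {
    S[1][IDX(i, 0)] = -open - i * ext;
    P[1][IDX(i, 0)] = 1;
  }
  for (int j = 1; j <= lb; ++j) {
    S[2][IDX(0, j)] = -open - j * ext;
    P[2][IDX(0, j)] = 2;
  }
  for (int i = 1; i <= la; ++i) {
    for (int j = 1; j <= lb; ++j) {
      const int d = IDX(i - 1, j - 1), u = IDX(i - 1, j), l = IDX(i, j - 1),
                c = IDX(i, j);
      double pm = S[0][d], px = S[1][d], py = S[2][d];
      double prev = std::max(std::max(pm, px), py);
      S[0][c] = prev + colScore(i - 1, j - 1);
      P[0][c] = (prev == pm) ? 0 : (prev == px ? 1 : 2);
      double fm = S[0][u] - open - ext, fx = S[1][u] - ext,
             fy = S[2][u] - open - ext;
      S[1][c] = std::max(std::max(fm, fx), fy);
      P[1][c] = (S[1][c] == fx) ? 1 : (S[1][c] == fm ? 0 : 2);
      double gm = S[0][l] - open - ext, gx = S[1][l] - open - ext,
             gy = S[2][l] - ext;
      S[2][c] = std::max(std::max(gm, gx), gy);
      P[2][c] = (S[2][c] == gy) ? 2 : (S[2][c] == gm ? 0 : 1);
    }
  }
  const int e = IDX(la, lb);
  double sm = S[0][e], sx = S[1][e], sy = S[2][e];
  double bestSc = std::max(std::max(sm, sx), sy);
  int st = (bestSc == sm) ? 0 : (bestSc == sx ? 1 : 2);
  std::vector<int> ops;
  int i = la, j = lb;
  while (i > 0 || j > 0) {
    if (st == 0) {
      signed char p = P[0][IDX(i, j)];
      ops.push_back(1); --i; --j; st = p;
    } else if (st == 1) {
      signed char p = P[1][IDX(i, j)];
      ops.push_back(2); --i; st = p;
    } else {
      signed char p = P[2][IDX(i, j)];
      ops.push_back(3); --j; st = p;
    }
  }
  std::reverse(ops.begin(), ops.end());
  #undef IDX
  return List::create(_["score"] = bestSc, _["ops"] = wrap(ops));
}
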