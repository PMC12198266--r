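#include <Rcpp.h>
#include <vector>
#include <utility>
using namespace Rcpp;

// Three-state (Gotoh) global alignment of two residue profiles under an
// affine gap model: a gap of length k costs gap_open + k * gap_ext.
//
// Profiles are integer matrices (rows = sequences, cols = alignment
// columns); values 0..19 index the amino-acid alphabet, anything else
// (gap, non-standard residue) contributes nothing to the column score but
// still counts in the per-column normalisation.
//
// Column score: sum_{a,b} fA(a,i) * fB(b,j) * S(a,b), with frequencies
// normalised by the full row count, so gap-rich columns score low.
//
// Tie-breaking is fixed: on equal scores prefer the diagonal (match)
// state, then the "up" state (consume a column of A), then "left"
// (consume a column of B), both when taking state maxima and at the
// final cell.  This makes the traceback deterministic.

static const double NEG_INF = -1e300;

static inline int argmax3(double m, double x, double y) {
  // preference order M > X > Y on ties
  if (m >= x && m >= y) return 0;
  if (x >= y) return 1;
  return 2;
}

// [[Rcpp::export]]
List profile_align_cpp(IntegerMatrix A, IntegerMatrix B, NumericMatrix S,
                       double gap_open, double gap_ext) {
  const int La = A.ncol(), Lb = B.ncol();
  const int ra = A.nrow(), rb = B.nrow();
  if (ra < 1 || rb < 1) stop("profiles must have at least one row");
  if (S.nrow() != 20 || S.ncol() != 20) stop("substitution matrix must be 20x20");

  // degenerate empty profiles: all-gap path
  if (La == 0 || Lb == 0) {
    IntegerVector pa(La + Lb, 0), pb(La + Lb, 0);
    double sc = 0.0;
    for (int i = 0; i < La; ++i) pa[i] = i + 1;
    for (int j = 0; j < Lb; ++j) pb[La + j] = j + 1;
    if (La > 0) sc = -(gap_open + La * gap_ext);
    if (Lb > 0) sc = -(gap_open + Lb * gap_ext);
    return List::create(_["score"] = sc, _["path_a"] = pa, _["path_b"] = pb);
  }

  // sparse residue frequencies per column of A
  std::vector< std::vector< std::pair<int, double> > > colsA(La);
  for (int i = 0; i < La; ++i) {
    double cnt[20] = {0};
    for (int r = 0; r < ra; ++r) {
      int v = A(r, i);
      if (v >= 0 && v < 20) cnt[v] += 1.0;
    }
    for (int a = 0; a < 20; ++a)
      if (cnt[a] > 0) colsA[i].push_back(std::make_pair(a, cnt[a] / ra));
  }

  // PB(a, j) = sum_b S(a, b) * freqB(b, j)
  std::vector<double> PB((size_t)20 * Lb, 0.0);
  for (int j = 0; j < Lb; ++j) {
    double cnt[20] = {0};
    for (int r = 0; r < rb; ++r) {
      int v = B(r, j);
      if (v >= 0 && v < 20) cnt[v] += 1.0;
    }
    for (int b = 0; b < 20; ++b) {
      if (cnt[b] > 0) {
        double f = cnt[b] / rb;
        for (int a = 0; a < 20; ++a) PB[(size_t)a * Lb + j] += S(a, b) * f;
      }
    }
  }

  const size_t W = (size_t)(Lb + 1);
  const size_t NC = (size_t)(La + 1) * W;
  std::vector<double> M(NC, NEG_INF), X(NC, NEG_INF), Y(NC, NEG_INF);
  // predecessor state per (cell, state)
  std::vector<unsigned char> pM(NC, 0), pX(NC, 0), pY(NC, 0);

  M[0] = 0.0;
  for (int i = 1; i <= La; ++i) {
    X[(size_t)i * W] = -(gap_open + i * gap_ext);
    pX[(size_t)i * W] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= Lb; ++j) {
    Y[(size_t)j] = -(gap_open + j * gap_ext);
    pY[(size_t)j] = (j == 1) ? 0 : 2;
  }

  const double oe = gap_open + gap_ext;
  for (int i = 1; i <= La; ++i) {
    const size_t row = (size_t)i * W, prow = (size_t)(i - 1) * W;
    const std::vector< std::pair<int, double> >& ca = colsA[i - 1];
    for (int j = 1; j <= Lb; ++j) {
      // match score for columns (i-1, j-1)
      double sc = 0.0;
      for (size_t k = 0; k < ca.size(); ++k)
        sc += ca[k].second * PB[(size_t)ca[k].first * Lb + (j - 1)];

      // M
      {
        double m = M[prow + j - 1], x = X[prow + j - 1], y = Y[prow + j - 1];
        int s = argmax3(m, x, y);
        double best = (s == 0) ? m : (s == 1 ? x : y);
        M[row + j] = (best <= NEG_INF / 2) ? NEG_INF : best + sc;
        pM[row + j] = (unsigned char)s;
      }
      // X: consume column of A, gap in B
      {
        double m = M[prow + j] - oe, x = X[prow + j] - gap_ext, y = Y[prow + j] - oe;
        int s = argmax3(m, x, y);
        X[row + j] = (s == 0) ? m : (s == 1 ? x : y);
        pX[row + j] = (unsigned char)s;
      }
      // Y: consume column of B, gap in A
      {
        double m = M[row + j - 1] - oe, x = X[row + j - 1] - oe, y = Y[row + j - 1] - gap_ext;
        int s = argmax3(m, x, y);
        Y[row + j] = (s == 0) ? m : (s == 1 ? x : y);
        pY[row + j] = (unsigned char)s;
      }
    }
  }

  size_t end = (size_t)La * W + Lb;
  int state = argmax3(M[end], X[end], Y[end]);
  double score = (state == 0) ? M[end] : (state == 1 ? X[end] : Y[end]);

  std::vector<int> ra_path, rb_path;
  int i = La, j = Lb;
  while (i > 0 || j > 0) {
    size_t cell = (size_t)i * W + j;
    if (state == 0) {
      ra_path.push_back(i); rb_path.push_back(j);
      state = pM[cell]; --i; --j;
    } else if (state == 1) {
      ra_path.push_back(i); rb_path.push_back(0);
      state = pX[cell]; --i;
    } else {
      ra_path.push_back(0); rb_path.push_back(j);
      state = pY[cell]; --j;
    }
  }

  int n = (int)ra_path.size();
  IntegerVector pa(n), pb(n);
  for (int k = 0; k < n; ++k) {
    pa[k] = ra_path[n - 1 - k];
    pb[k] = rb_path[n - 1 - k];
  }
  return List::create(_["score"] = score, _["path_a"] = pa, _["path_b"] = pb);
}
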