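#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch/Gotoh) profile-profile alignment with affine gaps.
// profA, profB: residue-frequency matrices (alphabet x columns); column sums
// may be < 1 when a profile column contains gaps (gaps contribute zero score).
// submat: alphabet x alphabet substitution scores, same row order as profiles.
// band: half-width of the diagonal band explored (<= 0 means full DP); the
// band is widened by the length difference so the corner stays reachable.
// Returns the edit path from the start as integers: 0 = align columns,
// 1 = column from A against a gap, 2 = column from B against a gap,
// plus the alignment score.
// [[Rcpp::export(name = ".profile_align_path")]]
List profile_align_path(NumericMatrix profA, NumericMatrix profB,
                        NumericMatrix submat,
                        double gap_open, double gap_ext, int band) {
  const int K = submat.nrow();
  const int la = profA.ncol(), lb = profB.ncol();
  const double NEG = -1e30;
  long w = (band <= 0) ? (long)la + lb : (long)band + std::abs(la - lb);

  // SB(a, j) = sum_b submat(a, b) * profB(b, j)
  NumericMatrix SB(K, lb);
  for (int j = 0; j < lb; ++j)
    for (int b = 0; b < K; ++b) {
      double f = profB(b, j);
      if (f != 0.0)
        for (int a = 0; a < K; ++a) SB(a, j) += submat(a, b) * f;
    }

  std::vector<double> M((la + 1) * (lb + 1), NEG);
  std::vector<double> X(M), Y(M);                 // X: gap in B, Y: gap in A
  std::vector<unsigned char> tbM(M.size()), tbX(M.size()), tbY(M.size());
  auto at = [lb](int i, int j) { return i * (lb + 1) + j; };

  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= la && i <= w; ++i) {
    X[at(i, 0)] = -gap_open - gap_ext * i;
    tbX[at(i, 0)] = 1;
  }
  for (int j = 1; j <= lb && j <= w; ++j) {
    Y[at(0, j)] = -gap_open - gap_ext * j;
    tbY[at(0, j)] = 2;
  }

  for (int i = 1; i <= la; ++i) {
    int jlo = std::max(1L, (long)i - w), jhi = std::min((long)lb, (long)i + w);
    for (int j = jlo; j <= jhi; ++j) {
      double sc = 0.0;
      for (int a = 0; a < K; ++a) {
        double f = profA(a, i - 1);
        if (f != 0.0) sc += f * SB(a, j - 1);
      }
      // M: align column i of A with column j of B
      double m0 = M[at(i - 1, j - 1)], x0 = X[at(i - 1, j - 1)],
             y0 = Y[at(i - 1, j - 1)];
      double best = m0; unsigned char tb = 0;
      if (x0 > best) { best = x0; tb = 1; }
      if (y0 > best) { best = y0; tb = 2; }
      M[at(i, j)] = best + sc;
      tbM[at(i, j)] = tb;
      // X: column i of A against gap
      double xo = M[at(i - 1, j)] - gap_open - gap_ext;
      double xe = X[at(i - 1, j)] - gap_ext;
      if (xo >= xe) { X[at(i, j)] = xo; tbX[at(i, j)] = 0; }
      else          { X[at(i, j)] = xe; tbX[at(i, j)] = 1; }
      // Y: column j of B against gap
      double yo = M[at(i, j - 1)] - gap_open - gap_ext;
      double ye = Y[at(i, j - 1)] - gap_ext;
      if (yo >= ye) { Y[at(i, j)] = yo; tbY[at(i, j)] = 0; }
      else          { Y[at(i, j)] = ye; tbY[at(i, j)] = 2; }
    }
  }

  // traceback
  int i = la, j = lb, state;
  double bm = M[at(i, j)], bx = X[at(i, j)], by = Y[at(i, j)];
  double score = bm; state = 0;
  if (bx > score) { score = bx; state = 1; }
  if (by > score) { score = by; state = 2; }
  std::vector<int> rev;
  while (i > 0 || j > 0) {
    if (state == 0) {
      unsigned char tb = tbM[at(i, j)];
      rev.push_back(0); --i; --j; state = tb;
    } else if (state == 1) {
      unsigned char tb = tbX[at(i, j)];
      rev.push_back(1); --i; state = (tb == 1) ? 1 : 0;
    } else {
      unsigned char tb = tbY[at(i, j)];
      rev.push_back(2); --j; state = (tb == 2) ? 2 : 0;
    }
  }
  return List::create(_["path"] = IntegerVector(rev.rbegin(), rev.rend()),
                      _["score"] = score);
}
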