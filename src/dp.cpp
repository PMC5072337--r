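#include <Rcpp.h>
using namespace Rcpp;

// Local (Smith-Waterman style) alignment with affine gaps over an arbitrary
// position-pair score matrix S (query rows x reference columns). A gap of
// length L costs gap_open + (L-1) * gap_ext. Alignments start and end in a
// match cell; the empty alignment scores 0.
//
// Used for sequence-vs-profile scoring (S[i,j] = emission log-odds of query
// residue i at profile column j) and for profile-vs-profile scoring
// (S[i,j] = co-emission log-odds of column pair i,j).
//
// Returns best score, the 1-based inclusive envelopes on both axes, and the
// matched (i,j) pairs along the traceback.
// [[Rcpp::export(name = ".sw_affine")]]
List sw_affine(NumericMatrix S, double gap_open, double gap_ext) {
  const int n = S.nrow(), m = S.ncol();
  if (n == 0 || m == 0) {
    return List::create(_["score"] = 0.0,
                        _["q_start"] = 0, _["q_end"] = 0,
                        _["r_start"] = 0, _["r_end"] = 0,
                        _["pairs"] = IntegerMatrix(0, 2));
  }
  const double NEG = -1e30;
  // state matrices, (n+1) x (m+1), index [i*(m+1)+j]
  std::vector<double> M((n + 1) * (m + 1), NEG);
  std::vector<double> X((n + 1) * (m + 1), NEG); // gap in reference (consume query)
  std::vector<double> Y((n + 1) * (m + 1), NEG); // gap in query (consume reference)
  // traceback: 0 = start (from empty), 1 = from M, 2 = from X, 3 = from Y
  std::vector<signed char> tbM((n + 1) * (m + 1), 0);
  std::vector<signed char> tbX((n + 1) * (m + 1), 0);
  std::vector<signed char> tbY((n + 1) * (m + 1), 0);

  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int idx = i * (m + 1) + j;
      const int dg = (i - 1) * (m + 1) + (j - 1);
      const int up = (i - 1) * (m + 1) + j;
      const int lf = i * (m + 1) + (j - 1);
      // M: consume (i, j)
      double mv = 0.0; signed char mt = 0;
      if (M[dg] > mv) { mv = M[dg]; mt = 1; }
      if (X[dg] > mv) { mv = X[dg]; mt = 2; }
      if (Y[dg] > mv) { mv = Y[dg]; mt = 3; }
      M[idx] = S(i - 1, j - 1) + mv;
      tbM[idx] = mt;
      // X: consume query row i only
      double xo = M[up] - gap_open, xe = X[up] - gap_ext;
      if (xo >= xe) { X[idx] = xo; tbX[idx] = 1; }
      else          { X[idx] = xe; tbX[idx] = 2; }
      // Y: consume reference column j only
      double yo = M[lf] - gap_open, ye = Y[lf] - gap_ext;
      if (yo >= ye) { Y[idx] = yo; tbY[idx] = 1; }
      else          { Y[idx] = ye; tbY[idx] = 3; }
      if (M[idx] > best) { best = M[idx]; bi = i; bj = j; }
    }
  }
  std::vector<int> pi, pj;
  int q1 = 0, q2 = 0, r1 = 0, r2 = 0;
  if (best > 0.0) {
    int i = bi, j = bj, state = 1;
    q2 = bi; r2 = bj;
    while (true) {
      const int idx = i * (m + 1) + j;
      if (state == 1) {
        pi.push_back(i); pj.push_back(j);
        signed char prev = tbM[idx];
        q1 = i; r1 = j;
        --i; --j;
        if (prev == 0) break;
        state = prev;
      } else if (state == 2) {
        state = tbX[idx];
        --i;
      } else {
        state = tbY[idx];
        --j;
      }
    }
    std::reverse(pi.begin(), pi.end());
    std::reverse(pj.begin(), pj.end());
  }
  IntegerMatrix pairs(pi.size(), 2);
  for (size_t k = 0; k < pi.size(); ++k) {
    pairs(k, 0) = pi[k];
    pairs(k, 1) = pj[k];
  }
  return List::create(_["score"] = best,
                      _["q_start"] = q1, _["q_end"] = q2,
                      _["r_start"] = r1, _["r_end"] = r2,
                      _["pairs"] = pairs);
}

// Batch variant returning only scores for many queries against one score
// matrix builder is done in R; this helper scores one emission matrix per
// call but avoids the traceback bookkeeping.
// [[Rcpp::export(name = ".sw_affine_score")]]
double sw_affine_score(NumericMatrix S, double gap_open, double gap_ext) {
  const int n = S.nrow(), m = S.ncol();
  if (n == 0 || m == 0) return 0.0;
  const double NEG = -1e30;
  std::vector<double> Mprev(m + 1, NEG), Mcur(m + 1, NEG);
  std::vector<double> Xprev(m + 1, NEG), Xcur(m + 1, NEG);
  std::vector<double> Yprev(m + 1, NEG), Ycur(m + 1, NEG);
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    Mcur[0] = NEG; Xcur[0] = NEG; Ycur[0] = NEG;
    for (int j = 1; j <= m; ++j) {
      double mv = 0.0;
      if (Mprev[j - 1] > mv) mv = Mprev[j - 1];
      if (Xprev[j - 1] > mv) mv = Xprev[j - 1];
      if (Yprev[j - 1] > mv) mv = Yprev[j - 1];
      Mcur[j] = S(i - 1, j - 1) + mv;
      double xo = Mprev[j] - gap_open, xe = Xprev[j] - gap_ext;
      Xcur[j] = xo >= xe ? xo : xe;
      double yo = Mcur[j - 1] - gap_open, ye = Ycur[j - 1] - gap_ext;
      Ycur[j] = yo >= ye ? yo : ye;
      if (Mcur[j] > best) best = Mcur[j];
    }
    std::swap(Mprev, Mcur);
    std::swap(Xprev, Xcur);
    std::swap(Yprev, Ycur);
  }
  return best;
}
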