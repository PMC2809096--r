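#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Single-hit local (Plan7-style) Viterbi over a profile HMM.
//
// mLO, iLO: L x 20 match / insert emission log-odds (bits).
// tr:       L x 7 transition log2-probabilities out of node k (1-based row k):
//           columns M->M, M->I, M->D, I->M, I->I, D->M, D->D.
// pep:      residue codes, 0..19 canonical AA, 20 = X (scores 0 bits at any
//           emitting state), 21 = '*' (alignments must not cross it).
//
// Entry: uniform over match states, log2(1/L); exit from any match state is
// free. Returns the best-scoring local path and the peptide span it emits;
// score of -Inf if no strictly positive-scoring path exists.

// [[Rcpp::export(name = ".viterbi_local_cpp")]]
List viterbi_local_cpp(NumericMatrix mLO, NumericMatrix iLO,
                       NumericMatrix tr, IntegerVector pep) {
  const int L = mLO.nrow();
  const int n = pep.size();
  const double NEG = -std::numeric_limits<double>::infinity();
  const double entry = -std::log2((double)L);

  std::vector<double> VM(L, NEG), VI(L, NEG), VD(L, NEG);
  std::vector<double> VMp(L, NEG), VIp(L, NEG), VDp(L, NEG);
  std::vector<int> BM(L, -1), BI(L, -1), BD(L, -1);
  std::vector<int> BMp(L, -1), BIp(L, -1), BDp(L, -1);

  double best = NEG;
  int bBeg = -1, bEnd = -1, bState = -1;

  for (int i = 0; i < n; i++) {
    const int c = pep[i];
    const bool star = (c == 21);
    const bool isx  = (c == 20);
    for (int k = 0; k < L; k++) {
      // match state k (0-based)
      double v = entry;   // fresh local entry emitting residue i at M_k
      int b = i;
      if (k > 0) {
        double a = VMp[k - 1] + tr(k - 1, 0);
        if (a > v) { v = a; b = BMp[k - 1]; }
        a = VIp[k - 1] + tr(k - 1, 3);
        if (a > v) { v = a; b = BIp[k - 1]; }
        a = VDp[k - 1] + tr(k - 1, 5);
        if (a > v) { v = a; b = BDp[k - 1]; }
      }
      if (star || v == NEG) {
        VM[k] = NEG; BM[k] = -1;
      } else {
        VM[k] = v + (isx ? 0.0 : mLO(k, c));
        BM[k] = b;
      }
      // insert state k
      double vi = NEG; int bi = -1;
      {
        double a = VMp[k] + tr(k, 1);
        if (a > vi) { vi = a; bi = BMp[k]; }
        a = VIp[k] + tr(k, 4);
        if (a > vi) { vi = a; bi = BIp[k]; }
      }
      if (star || vi == NEG) {
        VI[k] = NEG; BI[k] = -1;
      } else {
        VI[k] = vi + (isx ? 0.0 : iLO(k, c));
        BI[k] = bi;
      }
      // delete state k (no emission; same row i)
      double vd = NEG; int bd = -1;
      if (k > 0) {
        double a = VM[k - 1] + tr(k - 1, 2);
        if (a > vd) { vd = a; bd = BM[k - 1]; }
        a = VD[k - 1] + tr(k - 1, 6);
        if (a > vd) { vd = a; bd = BD[k - 1]; }
      }
      VD[k] = vd; BD[k] = bd;

      if (VM[k] > best) { best = VM[k]; bBeg = BM[k]; bEnd = i; bState = k; }
    }
    std::swap(VM, VMp); std::swap(VI, VIp); std::swap(VD, VDp);
    std::swap(BM, BMp); std::swap(BI, BIp); std::swap(BD, BDp);
  }

  if (!(best > 0.0)) {
    return List::create(_["score"] = NEG,
                        _["begin"] = NA_INTEGER, _["end"] = NA_INTEGER,
                        _["endState"] = NA_INTEGER);
  }
  return List::create(_["score"] = best,
                      _["begin"] = bBeg + 1, _["end"] = bEnd + 1,
                      _["endState"] = bState + 1);
}
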