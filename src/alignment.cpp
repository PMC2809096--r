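#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps (Gotoh), peptide vs
// peptide. A gap of length g costs gapOpen + g * gapExtend (BLAST
// convention). Tracks the begin coordinates of the optimal local path so
// spans are reported without a full traceback.
//
// q, r:    0-based integer residue codes indexing `subst`.
// Returns raw score and 1-based closed spans on query and reference;
// score 0 with empty spans if no positive-scoring pair exists.

// [[Rcpp::export(name = ".sw_local_cpp")]]
List sw_local_cpp(IntegerVector q, IntegerVector r, NumericMatrix subst,
                  double gapOpen, double gapExtend) {
  const int n = q.size(), m = r.size();
  const double gapFirst = gapOpen + gapExtend;
  const double NEG = -1e30;

  // rolling rows over j (reference); begin coordinates packed as i*(m+2)+j
  std::vector<double> H(m + 1, 0.0), Hp(m + 1, 0.0);
  std::vector<double> F(m + 1, NEG);        // gap in reference, per column
  std::vector<long>  BH(m + 1, -1), BHp(m + 1, -1);
  std::vector<long>  BF(m + 1, -1);

  double best = 0.0;
  long bestBeg = -1;
  int bi = -1, bj = -1;

  for (int i = 1; i <= n; i++) {
    double E = NEG;          // gap in query ending at (i, j), row-local
    long BE = -1;
    H[0] = 0.0; BH[0] = -1;
    for (int j = 1; j <= m; j++) {
      // E: gap in query (consumes reference)
      double e1 = H[j - 1] - gapFirst;    // open from H[i][j-1]
      double e2 = E - gapExtend;
      if (e1 >= e2) { E = e1; BE = BH[j - 1]; }
      else          { E = e2; /* BE unchanged */ }
      // F: gap in reference (consumes query)
      double f1 = Hp[j] - gapFirst;   // open from H[i-1][j]
      double f2 = F[j] - gapExtend;
      if (f1 >= f2) { F[j] = f1; BF[j] = BHp[j]; }
      else          { F[j] = f2; /* BF[j] unchanged */ }
      // H
      double diag = Hp[j - 1] + subst(q[i - 1], r[j - 1]);
      long bdiag = (BHp[j - 1] == -1) ? (long)(i - 1) * (m + 2) + (j - 1)
                                      : BHp[j - 1];
      double h = 0.0; long bh = -1;
      if (diag > h) { h = diag; bh = bdiag; }
      if (E > h)    { h = E;    bh = BE; }
      if (F[j] > h) { h = F[j]; bh = BF[j]; }
      H[j] = h; BH[j] = bh;
      if (h > best) { best = h; bestBeg = bh; bi = i; bj = j; }
    }
    std::swap(H, Hp); std::swap(BH, BHp);
  }

  if (!(best > 0.0) || bestBeg < 0) {
    return List::create(_["score"] = 0.0,
                        _["qBegin"] = NA_INTEGER, _["qEnd"] = NA_INTEGER,
                        _["rBegin"] = NA_INTEGER, _["rEnd"] = NA_INTEGER);
  }
  int qb = (int)(bestBeg / (m + 2)) + 1;
  int rb = (int)(bestBeg % (m + 2)) + 1;
  return List::create(_["score"] = best,
                      _["qBegin"] = qb, _["qEnd"] = bi,
                      _["rBegin"] = rb, _["rEnd"] = bj);
}

// ---------------------------------------------------------------------
// Chained translated-alignment objective used by frameshift correction.
// Per stop-free segment of the three forward frames, the best local
// alignment (score + reference span) is collected; HSPs are chained
// along the reference. Overlapping reference residues are penalised at
// overlapPenalty per residue (an upper bound on any per-residue
// contribution, so double counting never pays) and each chain join costs
// junctionPenalty (the price of positing one frameshift), giving greedy
// correction a gradient: rejoining two fragments reclaims the junction
// cost, while "bridging" garbled codons with a wrong-sign edit does not.
// HSPs below chainFloor are excluded from the chain: weak spurious
// segment alignments would otherwise offer an endless supply of tiny
// "improvements" around their boundaries.

struct SpanScore { double score; int rb; int re; };

// local alignment score + reference span with flat arrays (ns = number
// of residue codes = stride of subst, row-major)
static SpanScore sw_span_flat(const int *q, int n, const int *r, int m,
                              const double *subst, int ns,
                              double gapOpen, double gapExtend,
                              std::vector<double> &H,
                              std::vector<double> &Hp,
                              std::vector<double> &F,
                              std::vector<int> &BH,
                              std::vector<int> &BHp,
                              std::vector<int> &BF) {
  const double gapFirst = gapOpen + gapExtend;
  const double NEG = -1e30;
  H.assign(m + 1, 0.0); Hp.assign(m + 1, 0.0); F.assign(m + 1, NEG);
  BH.assign(m + 1, -1); BHp.assign(m + 1, -1); BF.assign(m + 1, -1);
  double best = 0.0; int bb = -1, bj = -1;
  for (int i = 1; i <= n; i++) {
    double E = NEG; int BE = -1;
    const double *srow = subst + (size_t)q[i - 1] * ns;
    for (int j = 1; j <= m; j++) {
      double e1 = H[j - 1] - gapFirst, e2 = E - gapExtend;
      if (e1 >= e2) { E = e1; BE = BH[j - 1]; } else E = e2;
      double f1 = Hp[j] - gapFirst, f2 = F[j] - gapExtend;
      if (f1 >= f2) { F[j] = f1; BF[j] = BHp[j]; } else F[j] = f2;
      double diag = Hp[j - 1] + srow[r[j - 1]];
      int bdiag = (BHp[j - 1] == -1) ? j : BHp[j - 1];
      double h = 0.0; int bh = -1;
      if (diag > h) { h = diag; bh = bdiag; }
      if (E > h)    { h = E;    bh = BE; }
      if (F[j] > h) { h = F[j]; bh = BF[j]; }
      H[j] = h; BH[j] = bh;
      if (h > best) { best = h; bb = bh; bj = j; }
    }
    std::swap(H, Hp); std::swap(BH, BHp);
  }
  SpanScore out; out.score = best; out.rb = bb; out.re = bj;
  return out;
}

// score-only local alignment (no span tracking), used as a prefilter
static double sw_score_flat(const int *q, int n, const int *r, int m,
                            const double *subst, int ns,
                            double gapOpen, double gapExtend,
                            std::vector<double> &H,
                            std::vector<double> &Hp,
                            std::vector<double> &F) {
  const double gapFirst = gapOpen + gapExtend;
  const double NEG = -1e30;
  H.assign(m + 1, 0.0); Hp.assign(m + 1, 0.0); F.assign(m + 1, NEG);
  double best = 0.0;
  for (int i = 1; i <= n; i++) {
    double E = NEG;
    const double *srow = subst + (size_t)q[i - 1] * ns;
    for (int j = 1; j <= m; j++) {
      double e1 = H[j - 1] - gapFirst, e2 = E - gapExtend;
      E = (e1 >= e2) ? e1 : e2;
      double f1 = Hp[j] - gapFirst, f2 = F[j] - gapExtend;
      F[j] = (f1 >= f2) ? f1 : f2;
      double h = Hp[j - 1] + srow[r[j - 1]];
      if (E > h) h = E;
      if (F[j] > h) h = F[j];
      if (h < 0.0) h = 0.0;
      H[j] = h;
      if (h > best) best = h;
    }
    std::swap(H, Hp);
  }
  return best;
}

struct ChainCtx {
  std::vector<double> H, Hp, F;
  std::vector<int> BH, BHp, BF;
  std::vector<int> seg;
  std::vector<SpanScore> hsps;
  std::vector<double> dp;
};

static inline int baseCode(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default:  return -1;
  }
}

static double chain_score(const std::string &dna,
                          const std::vector<int> &ref,
                          const double *subst, int ns,
                          double gapOpen, double gapExtend, int minSegAA,
                          const int *codonCode, double overlapPenalty,
                          double junctionPenalty, double chainFloor,
                          ChainCtx &ctx) {
  const int n = (int)dna.size();
  ctx.hsps.clear();
  for (int off = 0; off < 3; off++) {
    ctx.seg.clear();
    for (int p = off; p + 2 < n; p += 3) {
      int b0 = baseCode(dna[p]), b1 = baseCode(dna[p + 1]),
          b2 = baseCode(dna[p + 2]);
      int code = (b0 < 0 || b1 < 0 || b2 < 0) ? 20
        : codonCode[16 * b0 + 4 * b1 + b2];
      if (code == 21) {
        if ((int)ctx.seg.size() >= minSegAA) {
          double sc = sw_score_flat(ctx.seg.data(), (int)ctx.seg.size(),
                                    ref.data(), (int)ref.size(), subst,
                                    ns, gapOpen, gapExtend, ctx.H,
                                    ctx.Hp, ctx.F);
          if (sc >= chainFloor) {
            SpanScore s = sw_span_flat(ctx.seg.data(),
                                       (int)ctx.seg.size(), ref.data(),
                                       (int)ref.size(), subst, ns,
                                       gapOpen, gapExtend, ctx.H,
                                       ctx.Hp, ctx.F, ctx.BH, ctx.BHp,
                                       ctx.BF);
            ctx.hsps.push_back(s);
          }
        }
        ctx.seg.clear();
      } else ctx.seg.push_back(code);
    }
    if ((int)ctx.seg.size() >= minSegAA) {
      double sc = sw_score_flat(ctx.seg.data(), (int)ctx.seg.size(),
                                ref.data(), (int)ref.size(), subst, ns,
                                gapOpen, gapExtend, ctx.H, ctx.Hp,
                                ctx.F);
      if (sc >= chainFloor) {
        SpanScore s = sw_span_flat(ctx.seg.data(), (int)ctx.seg.size(),
                                   ref.data(), (int)ref.size(), subst,
                                   ns, gapOpen, gapExtend, ctx.H,
                                   ctx.Hp, ctx.F, ctx.BH, ctx.BHp,
                                   ctx.BF);
        ctx.hsps.push_back(s);
      }
    }
  }
  if (ctx.hsps.empty()) return 0.0;
  std::sort(ctx.hsps.begin(), ctx.hsps.end(),
            [](const SpanScore &a, const SpanScore &b) {
              return a.rb < b.rb || (a.rb == b.rb && a.re < b.re);
            });
  const int K = (int)ctx.hsps.size();
  ctx.dp.assign(K, 0.0);
  double best = 0.0;
  for (int i = 0; i < K; i++) {
    ctx.dp[i] = ctx.hsps[i].score;
    for (int j = 0; j < i; j++) {
      if (ctx.hsps[j].re >= ctx.hsps[i].re) continue;
      int overlap = ctx.hsps[j].re - ctx.hsps[i].rb + 1;
      if (overlap < 0) overlap = 0;
      double cand = ctx.dp[j] + ctx.hsps[i].score -
        overlapPenalty * overlap - junctionPenalty;
      if (cand > ctx.dp[i]) ctx.dp[i] = cand;
    }
    if (ctx.dp[i] > best) best = ctx.dp[i];
  }
  return best;
}

static std::vector<double> flatten_rowmajor(const NumericMatrix &subst) {
  const int ns = subst.nrow();
  std::vector<double> sm((size_t)ns * ns);
  for (int a = 0; a < ns; a++)
    for (int b = 0; b < ns; b++)
      sm[(size_t)a * ns + b] = subst(a, b);
  return sm;
}

// [[Rcpp::export(name = ".translated_chain_score_cpp")]]
double translated_chain_score_cpp(std::string dna, IntegerVector refCodes,
                                  NumericMatrix subst, double gapOpen,
                                  double gapExtend, int minSegAA,
                                  IntegerVector codonCode,
                                  double overlapPenalty,
                                  double junctionPenalty,
                                  double chainFloor) {
  std::vector<double> sm = flatten_rowmajor(subst);
  std::vector<int> ref(refCodes.begin(), refCodes.end());
  std::vector<int> cc(codonCode.begin(), codonCode.end());
  ChainCtx ctx;
  return chain_score(dna, ref, sm.data(), subst.nrow(), gapOpen,
                     gapExtend, minSegAA, cc.data(), overlapPenalty,
                     junctionPenalty, chainFloor, ctx);
}

// Evaluate every single-base deletion and duplication in [lo, hi]
// (1-based, inclusive) of `dna` under the chained objective and return
// the best strictly-improving edit relative to `baseScore`. Edits that
// produce identical sequences (any position inside one homopolymer run)
// are evaluated once, at the run's first in-window position; among
// equal-gain edits the longer run wins, then the leftmost position.
// kind: 1 = delete, 2 = duplicate. Returns (gain, pos, kind, runLength,
// score); gain = 0 when nothing improves.

// [[Rcpp::export(name = ".best_edit_cpp")]]
NumericVector best_edit_cpp(std::string dna, int lo, int hi,
                            double baseScore, IntegerVector refCodes,
                            NumericMatrix subst, double gapOpen,
                            double gapExtend, int minSegAA,
                            IntegerVector codonCode,
                            double overlapPenalty,
                            double junctionPenalty,
                            double chainFloor) {
  const int n = (int)dna.size();
  std::vector<double> sm = flatten_rowmajor(subst);
  std::vector<int> ref(refCodes.begin(), refCodes.end());
  std::vector<int> cc(codonCode.begin(), codonCode.end());
  ChainCtx ctx;

  // homopolymer run structure
  std::vector<int> runStart(n, 0), runLen(n, 1);
  for (int i = 1; i < n; i++)
    runStart[i] = (dna[i] == dna[i - 1]) ? runStart[i - 1] : i;
  for (int i = n - 2; i >= 0; i--)
    if (dna[i] == dna[i + 1]) runLen[i] = runLen[i + 1] + 1;
  for (int i = 0; i < n; i++) runLen[i] = runLen[runStart[i]];

  if (lo < 1) lo = 1;
  if (hi > n) hi = n;
  const double eps = 1e-9;
  double bestGain = 0.0, bestScore = 0.0;
  int bestPos = -1, bestKind = 0, bestRun = 0;
  std::string cand;
  for (int pos = lo; pos <= hi; pos++) {
    // canonical representative per run (first in-window position)
    if (pos > lo && pos - 1 != runStart[pos - 1]) continue;
    for (int kind = 1; kind <= 2; kind++) {
      cand.clear();
      if (kind == 1) {
        cand.append(dna, 0, pos - 1);
        cand.append(dna, pos, n - pos);
      } else {
        cand.append(dna, 0, pos);
        cand.append(1, dna[pos - 1]);
        cand.append(dna, pos, n - pos);
      }
      double s = chain_score(cand, ref, sm.data(), subst.nrow(), gapOpen,
                             gapExtend, minSegAA, cc.data(),
                             overlapPenalty, junctionPenalty,
                             chainFloor, ctx);
      double gain = s - baseScore;
      if (gain <= eps) continue;
      bool better = gain > bestGain + eps;
      bool tie = !better && gain > bestGain - eps &&
        (runLen[pos - 1] > bestRun ||
         (runLen[pos - 1] == bestRun && pos < bestPos));
      if (better || tie) {
        bestGain = gain; bestScore = s; bestPos = pos;
        bestKind = kind; bestRun = runLen[pos - 1];
      }
    }
  }
  return NumericVector::create(bestGain, bestPos, bestKind, bestRun,
                               bestScore);
}
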