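#include <Rcpp.h>
using namespace Rcpp;

// Banded dynamic-programming recursion for dynamic time warping over a
// row-compressed layout. Row i (1..M) stores columns lo[i-1]..hi[i-1] of the
// virtual M x N matrix contiguously in a linear array (offset idx[i-1]).
// Cells outside the layout read as -Inf; Q(0,0) = 0 and the remainder of row
// 0 / column 0 is -Inf, forcing a global alignment that starts at (1,1).
//
// f holds the (penalized) pairwise similarity for every stored cell, in the
// same row-compressed order. Each step adds w(step) * f(i, j); ties in the
// maximisation prefer match over compression over expansion so tracebacks
// are deterministic and favour the diagonal.
//
// [[Rcpp::export]]
List dtw_dp_rcs(NumericVector f, IntegerVector lo, IntegerVector hi,
                int N, double wmatch, double wcomp, double wexp) {
  const int M = lo.size();
  const double NEG = R_NegInf;
  std::vector<long long> idx(M);
  long long total = 0;
  for (int i = 0; i < M; ++i) {
    idx[i] = total;
    total += hi[i] - lo[i] + 1;
  }
  if (total != (long long)f.size())
    stop("similarity array does not match layout size");
  std::vector<double> Q((size_t)total, NEG);
  std::vector<signed char> mv((size_t)total, -1); // 0 match, 1 comp, 2 exp

  for (int i = 1; i <= M; ++i) {
    const int l = lo[i - 1], h = hi[i - 1];
    const long long base = idx[i - 1];
    const int lprev = (i >= 2) ? lo[i - 2] : 0;
    const int hprev = (i >= 2) ? hi[i - 2] : 0;
    const long long bprev = (i >= 2) ? idx[i - 2] : 0;
    for (int j = l; j <= h; ++j) {
      const long long k = base + (j - l);
      const double fij = f[k];
      double qd = NEG, qu = NEG, ql = NEG;
      if (i == 1 && j == 1) {
        qd = 0.0; // Q(0,0)
      } else if (i >= 2) {
        if (j - 1 >= lprev && j - 1 <= hprev) qd = Q[bprev + (j - 1 - lprev)];
        if (j >= lprev && j <= hprev) qu = Q[bprev + (j - lprev)];
      }
      if (j - 1 >= l) ql = Q[k - 1];
      const double cm = (qd == NEG) ? NEG : qd + wmatch * fij;
      const double cc = (ql == NEG) ? NEG : ql + wcomp * fij;
      const double ce = (qu == NEG) ? NEG : qu + wexp * fij;
      double best = cm; int bmv = 0;
      if (cc > best) { best = cc; bmv = 1; }
      if (ce > best) { best = ce; bmv = 2; }
      Q[k] = best;
      mv[k] = (best == NEG) ? -1 : (signed char)bmv;
    }
  }

  // final cell (M, N) must be stored and reachable
  if (N < lo[M - 1] || N > hi[M - 1])
    stop("layout does not contain the final cell (M, N)");
  long long kend = idx[M - 1] + (N - lo[M - 1]);
  double score = Q[kend];
  if (score == NEG)
    stop("no admissible alignment path: layout disconnects (1,1) from (M,N)");

  // traceback
  std::vector<int> pi, pj, pm;
  int i = M, j = N;
  while (true) {
    long long k = idx[i - 1] + (j - lo[i - 1]);
    pi.push_back(i); pj.push_back(j); pm.push_back(mv[k]);
    if (i == 1 && j == 1) break;
    switch (mv[k]) {
    case 0: --i; --j; break;
    case 1: --j; break;
    case 2: --i; break;
    default: stop("traceback reached an unset cell");
    }
  }
  std::reverse(pi.begin(), pi.end());
  std::reverse(pj.begin(), pj.end());
  std::reverse(pm.begin(), pm.end());

  return List::create(_["score"] = score,
                      _["i"] = wrap(pi), _["j"] = wrap(pj),
                      _["move"] = wrap(pm),
                      _["cells"] = (double)total);
}
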