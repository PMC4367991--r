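#include <Rcpp.h>
using namespace Rcpp;

// Payoff lookup: 2x2x2x2 array in R array order, dims (gA, bA, gB, bB);
// entry = payoff to player A of one pairwise encounter.
static inline double lu(const NumericVector &tab,
                        int gA, int bA, int gB, int bB) {
  return tab[(gA - 1) + 2 * (bA - 1) + 4 * (gB - 1) + 8 * (bB - 1)];
}

// One site's accumulated payoff over its four von Neumann neighbors with
// periodic wrap; neighbor order N, E, S, W (row - 1, col + 1, row + 1,
// col - 1), consistent with the R reference implementation.
static void payoffs(const IntegerMatrix &grp, const IntegerMatrix &beh,
                    const NumericVector &tab, NumericMatrix &pay) {
  const int L = grp.nrow(), M = grp.ncol();
  for (int j = 0; j < M; ++j) {
    const int jw = (j - 1 + M) % M, je = (j + 1) % M;
    for (int i = 0; i < L; ++i) {
      const int in = (i - 1 + L) % L, is = (i + 1) % L;
      const int g = grp(i, j), b = beh(i, j);
      double p = lu(tab, g, b, grp(in, j), beh(in, j));
      p += lu(tab, g, b, grp(i, je), beh(i, je));
      p += lu(tab, g, b, grp(is, j), beh(is, j));
      p += lu(tab, g, b, grp(i, jw), beh(i, jw));
      pay(i, j) = p;
    }
  }
}

// [[Rcpp::export(name = ".cpp_accumulate_payoffs")]]
NumericMatrix cpp_accumulate_payoffs(const IntegerMatrix grp,
                                     const IntegerMatrix beh,
                                     const NumericVector tab) {
  NumericMatrix pay(grp.nrow(), grp.ncol());
  payoffs(grp, beh, tab, pay);
  return pay;
}

// Synchronous unconditional imitation: every site adopts the behavior of the
// highest-payoff member of {self, N, E, S, W}. Ties keep self; among tied
// neighbors the first in N, E, S, W order wins (strict > comparison while
// scanning in that order).
static bool update(const IntegerMatrix &beh, const NumericMatrix &pay,
                   IntegerMatrix &nxt) {
  const int L = beh.nrow(), M = beh.ncol();
  bool changed = false;
  for (int j = 0; j < M; ++j) {
    const int jw = (j - 1 + M) % M, je = (j + 1) % M;
    for (int i = 0; i < L; ++i) {
      const int in = (i - 1 + L) % L, is = (i + 1) % L;
      double best = pay(i, j);
      int bb = beh(i, j);
      if (pay(in, j) > best) { best = pay(in, j); bb = beh(in, j); }
      if (pay(i, je) > best) { best = pay(i, je); bb = beh(i, je); }
      if (pay(is, j) > best) { best = pay(is, j); bb = beh(is, j); }
      if (pay(i, jw) > best) { best = pay(i, jw); bb = beh(i, jw); }
      nxt(i, j) = bb;
      if (bb != beh(i, j)) changed = true;
    }
  }
  return changed;
}

// Advance up to `steps` rounds of payoff accumulation + synchronous
// imitation, recording per-step behavior-1 fractions (population and per
// group). Stops early when an update leaves the grid unchanged (exact fixed
// point of the deterministic dynamics). Returns the number of steps actually
// performed, the fraction series, the final behavior grid and whether a
// fixed point was hit.
// [[Rcpp::export(name = ".cpp_simulate")]]
List cpp_simulate(const IntegerMatrix grp, const IntegerMatrix beh0,
                  const NumericVector tab, const int steps) {
  const int L = grp.nrow(), M = grp.ncol();
  const int n = L * M;
  int n1 = 0;
  for (int k = 0; k < n; ++k) n1 += (grp[k] == 1);
  const int n2 = n - n1;

  IntegerMatrix beh = clone(beh0), nxt(L, M);
  NumericMatrix pay(L, M);
  NumericVector rho(steps), rho_g1(steps), rho_g2(steps);

  int done = 0;
  bool fixed = false;
  for (int t = 0; t < steps; ++t) {
    payoffs(grp, beh, tab, pay);
    bool changed = update(beh, pay, nxt);
    std::copy(nxt.begin(), nxt.end(), beh.begin());
    int c1 = 0, c1g1 = 0;
    for (int k = 0; k < n; ++k) {
      if (beh[k] == 1) { ++c1; if (grp[k] == 1) ++c1g1; }
    }
    rho[t] = (double)c1 / n;
    rho_g1[t] = n1 > 0 ? (double)c1g1 / n1 : NA_REAL;
    rho_g2[t] = n2 > 0 ? (double)(c1 - c1g1) / n2 : NA_REAL;
    ++done;
    if (!changed) { fixed = true; break; }
  }
  return List::create(_["steps_done"] = done,
                      _["rho1"] = rho[Range(0, std::max(done - 1, 0))],
                      _["rho1_g1"] = rho_g1[Range(0, std::max(done - 1, 0))],
                      _["rho1_g2"] = rho_g2[Range(0, std::max(done - 1, 0))],
                      _["behavior"] = beh,
                      _["fixed_point"] = fixed);
}
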