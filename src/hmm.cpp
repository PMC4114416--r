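#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Frame-level HMM recursions in the log domain. Emission log-densities are
// computed vectorised on the R side; these loops only handle the lattice.

static inline double lse2(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  double m = a > b ? a : b;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

// logB: T x S frame log-emissions; logPi: entry log-probs; logA: S x S
// transition log-probs; logExit: per-state exit log-probs (the sequence must
// end by exiting). Returns total log-likelihood, log state occupancies,
// expected transition counts (linear domain) and expected exit counts.
// [[Rcpp::export]]
List forward_backward_c(NumericMatrix logB, NumericVector logPi,
                        NumericMatrix logA, NumericVector logExit) {
  const int T = logB.nrow(), S = logB.ncol();
  NumericMatrix alpha(T, S), beta(T, S);

  for (int s = 0; s < S; ++s) alpha(0, s) = logPi[s] + logB(0, s);
  for (int t = 1; t < T; ++t)
    for (int j = 0; j < S; ++j) {
      double acc = R_NegInf;
      for (int i = 0; i < S; ++i) {
        double v = alpha(t - 1, i) + logA(i, j);
        if (v != R_NegInf) acc = lse2(acc, v);
      }
      alpha(t, j) = acc + logB(t, j);
    }

  double ll = R_NegInf;
  for (int s = 0; s < S; ++s) ll = lse2(ll, alpha(T - 1, s) + logExit[s]);

  for (int s = 0; s < S; ++s) beta(T - 1, s) = logExit[s];
  for (int t = T - 2; t >= 0; --t)
    for (int i = 0; i < S; ++i) {
      double acc = R_NegInf;
      for (int j = 0; j < S; ++j) {
        double v = logA(i, j) + logB(t + 1, j) + beta(t + 1, j);
        if (v != R_NegInf) acc = lse2(acc, v);
      }
      beta(t, i) = acc;
    }

  NumericMatrix loggamma(T, S);
  for (int t = 0; t < T; ++t)
    for (int s = 0; s < S; ++s)
      loggamma(t, s) = alpha(t, s) + beta(t, s) - ll;

  NumericMatrix xi(S, S);
  for (int t = 0; t + 1 < T; ++t)
    for (int i = 0; i < S; ++i) {
      if (alpha(t, i) == R_NegInf) continue;
      for (int j = 0; j < S; ++j) {
        if (logA(i, j) == R_NegInf) continue;
        double v = alpha(t, i) + logA(i, j) + logB(t + 1, j) +
          beta(t + 1, j) - ll;
        if (v != R_NegInf) xi(i, j) += std::exp(v);
      }
    }

  NumericVector exitCount(S);
  for (int s = 0; s < S; ++s) {
    double v = alpha(T - 1, s) + logExit[s] - ll;
    exitCount[s] = (v == R_NegInf) ? 0.0 : std::exp(v);
  }

  return List::create(_["loglik"] = ll, _["loggamma"] = loggamma,
                      _["xi"] = xi, _["exit"] = exitCount);
}

// Max-probability state path. Ties broken toward the lowest state index
// (strict > while scanning predecessors in ascending order), so decoding is
// deterministic. beam is a log-width: states scoring more than beam below
// the per-frame best are pruned; R_PosInf disables pruning (exact).
// Returned path is 1-based.
// [[Rcpp::export]]
List viterbi_c(NumericMatrix logB, NumericVector logPi, NumericMatrix logA,
               NumericVector logExit, double beam) {
  const int T = logB.nrow(), S = logB.ncol();
  NumericMatrix delta(T, S);
  IntegerMatrix psi(T, S);

  for (int s = 0; s < S; ++s) delta(0, s) = logPi[s] + logB(0, s);
  if (R_finite(beam)) {
    double best = R_NegInf;
    for (int s = 0; s < S; ++s) if (delta(0, s) > best) best = delta(0, s);
    for (int s = 0; s < S; ++s)
      if (delta(0, s) < best - beam) delta(0, s) = R_NegInf;
  }

  for (int t = 1; t < T; ++t) {
    for (int j = 0; j < S; ++j) {
      double best = R_NegInf;
      int arg = 0;
      for (int i = 0; i < S; ++i) {
        if (delta(t - 1, i) == R_NegInf || logA(i, j) == R_NegInf) continue;
        double v = delta(t - 1, i) + logA(i, j);
        if (v > best) { best = v; arg = i; }
      }
      delta(t, j) = (best == R_NegInf) ? R_NegInf : best + logB(t, j);
      psi(t, j) = arg;
    }
    if (R_finite(beam)) {
      double best = R_NegInf;
      for (int s = 0; s < S; ++s) if (delta(t, s) > best) best = delta(t, s);
      for (int s = 0; s < S; ++s)
        if (delta(t, s) < best - beam) delta(t, s) = R_NegInf;
    }
  }

  double best = R_NegInf;
  int arg = 0;
  for (int s = 0; s < S; ++s) {
    if (delta(T - 1, s) == R_NegInf || logExit[s] == R_NegInf) continue;
    double v = delta(T - 1, s) + logExit[s];
    if (v > best) { best = v; arg = s; }
  }

  IntegerVector path(T);
  path[T - 1] = arg;
  for (int t = T - 1; t > 0; --t) path[t - 1] = psi(t, path[t]);
  for (int t = 0; t < T; ++t) path[t] += 1;

  return List::create(_["path"] = path, _["score"] = best);
}
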