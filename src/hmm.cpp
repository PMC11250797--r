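#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward for a two-state HMM on one chain.
// logemit: T x 2 log emission likelihoods; trans: 2 x 2 transition matrix
// (probabilities); init: length-2 initial distribution.
// Returns posterior state probabilities (gamma), summed expected transition
// counts (xi) and the chain log-likelihood.
// [[Rcpp::export(name = ".fb_two_state")]]
List fb_two_state(NumericMatrix logemit, NumericMatrix trans,
                  NumericVector init) {
  const int T = logemit.nrow();
  if (T == 0)
    return List::create(_["gamma"] = NumericMatrix(0, 2),
                        _["xi"] = NumericMatrix(2, 2), _["loglik"] = 0.0);

  NumericMatrix emit(T, 2);      // row-rescaled emissions
  NumericVector rowoff(T);       // per-row log offsets
  for (int t = 0; t < T; ++t) {
    double m = std::max(logemit(t, 0), logemit(t, 1));
    rowoff[t] = m;
    emit(t, 0) = std::exp(logemit(t, 0) - m);
    emit(t, 1) = std::exp(logemit(t, 1) - m);
  }

  NumericMatrix alpha(T, 2), beta(T, 2);
  NumericVector scale(T);

  alpha(0, 0) = init[0] * emit(0, 0);
  alpha(0, 1) = init[1] * emit(0, 1);
  scale[0] = alpha(0, 0) + alpha(0, 1);
  alpha(0, 0) /= scale[0];
  alpha(0, 1) /= scale[0];
  for (int t = 1; t < T; ++t) {
    for (int j = 0; j < 2; ++j) {
      alpha(t, j) = (alpha(t - 1, 0) * trans(0, j) +
                     alpha(t - 1, 1) * trans(1, j)) * emit(t, j);
    }
    scale[t] = alpha(t, 0) + alpha(t, 1);
    alpha(t, 0) /= scale[t];
    alpha(t, 1) /= scale[t];
  }

  beta(T - 1, 0) = 1.0;
  beta(T - 1, 1) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int i = 0; i < 2; ++i) {
      beta(t, i) = (trans(i, 0) * emit(t + 1, 0) * beta(t + 1, 0) +
                    trans(i, 1) * emit(t + 1, 1) * beta(t + 1, 1)) /
                   scale[t + 1];
    }
  }

  NumericMatrix gamma(T, 2);
  for (int t = 0; t < T; ++t) {
    double g0 = alpha(t, 0) * beta(t, 0);
    double g1 = alpha(t, 1) * beta(t, 1);
    double s = g0 + g1;
    gamma(t, 0) = g0 / s;
    gamma(t, 1) = g1 / s;
  }

  NumericMatrix xi(2, 2);
  for (int t = 0; t + 1 < T; ++t) {
    double denom = 0.0;
    double x[2][2];
    for (int i = 0; i < 2; ++i)
      for (int j = 0; j < 2; ++j) {
        x[i][j] = alpha(t, i) * trans(i, j) * emit(t + 1, j) * beta(t + 1, j);
        denom += x[i][j];
      }
    for (int i = 0; i < 2; ++i)
      for (int j = 0; j < 2; ++j) xi(i, j) += x[i][j] / denom;
  }

  double loglik = 0.0;
  for (int t = 0; t < T; ++t) loglik += std::log(scale[t]) + rowoff[t];

  return List::create(_["gamma"] = gamma, _["xi"] = xi,
                      _["loglik"] = loglik);
}

// Viterbi decoding for the same chain representation; returns the most
// probable state path (0-based state indices).
// [[Rcpp::export(name = ".viterbi_two_state")]]
IntegerVector viterbi_two_state(NumericMatrix logemit, NumericMatrix trans,
                                NumericVector init) {
  const int T = logemit.nrow();
  IntegerVector path(T);
  if (T == 0) return path;

  NumericMatrix delta(T, 2);
  IntegerMatrix psi(T, 2);
  double lt[2][2];
  for (int i = 0; i < 2; ++i)
    for (int j = 0; j < 2; ++j) lt[i][j] = std::log(trans(i, j));

  delta(0, 0) = std::log(init[0]) + logemit(0, 0);
  delta(0, 1) = std::log(init[1]) + logemit(0, 1);
  for (int t = 1; t < T; ++t) {
    for (int j = 0; j < 2; ++j) {
      double a = delta(t - 1, 0) + lt[0][j];
      double b = delta(t - 1, 1) + lt[1][j];
      if (a >= b) {
        delta(t, j) = a + logemit(t, j);
        psi(t, j) = 0;
      } else {
        delta(t, j) = b + logemit(t, j);
        psi(t, j) = 1;
      }
    }
  }
  path[T - 1] = delta(T - 1, 0) >= delta(T - 1, 1) ? 0 : 1;
  for (int t = T - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);
  return path;
}
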