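#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();
static const double TINY = 1e-300;

// Scaled forward-backward for one trace (Rabiner scaling; linear space).
// B: T x N per-frame emission densities; A: N x N transition probabilities;
// pi: length-N start probabilities. Returns the log-likelihood, posterior
// state probabilities gamma (T x N) and summed pairwise posteriors xi_sum
// (N x N).
// [[Rcpp::export]]
List hmm_forward_backward(NumericMatrix B, NumericMatrix A,
                          NumericVector pi) {
  int T = B.nrow(), N = B.ncol();
  NumericMatrix alpha(T, N), beta(T, N);
  std::vector<double> c(T);

  double s = 0.0;
  for (int j = 0; j < N; ++j) { alpha(0, j) = pi[j] * B(0, j); s += alpha(0, j); }
  if (s <= 0) s = TINY;
  c[0] = s;
  for (int j = 0; j < N; ++j) alpha(0, j) /= s;
  for (int t = 1; t < T; ++t) {
    s = 0.0;
    for (int j = 0; j < N; ++j) {
      double a = 0.0;
      for (int i = 0; i < N; ++i) a += alpha(t - 1, i) * A(i, j);
      a *= B(t, j);
      alpha(t, j) = a;
      s += a;
    }
    if (s <= 0) s = TINY;
    c[t] = s;
    for (int j = 0; j < N; ++j) alpha(t, j) /= s;
  }

  for (int j = 0; j < N; ++j) beta(T - 1, j) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int i = 0; i < N; ++i) {
      double b = 0.0;
      for (int j = 0; j < N; ++j) b += A(i, j) * B(t + 1, j) * beta(t + 1, j);
      beta(t, i) = b / c[t + 1];
    }
  }

  double loglik = 0.0;
  for (int t = 0; t < T; ++t) loglik += std::log(c[t]);

  NumericMatrix gamma(T, N);
  for (int t = 0; t < T; ++t) {
    double g = 0.0;
    for (int j = 0; j < N; ++j) { gamma(t, j) = alpha(t, j) * beta(t, j); g += gamma(t, j); }
    if (g > 0) for (int j = 0; j < N; ++j) gamma(t, j) /= g;
  }

  NumericMatrix xi_sum(N, N);
  for (int t = 0; t < T - 1; ++t)
    for (int i = 0; i < N; ++i) {
      if (alpha(t, i) <= 0) continue;
      for (int j = 0; j < N; ++j) {
        if (A(i, j) <= 0) continue;
        xi_sum(i, j) += alpha(t, i) * A(i, j) * B(t + 1, j) *
          beta(t + 1, j) / c[t + 1];
      }
    }

  return List::create(_["loglik"] = loglik, _["gamma"] = gamma,
                      _["xi_sum"] = xi_sum);
}

// Blur-aware variant: the emission density of frame t depends on the state
// pair (s_{t-1}, s_t). A frame during which the chain jumped between states
// with different FRET levels integrates part of each level, so its density
// is the uniform-mean mixture N(lambda E_i + (1-lambda) E_j, sigma),
// lambda ~ U(0,1), instead of a pure Gaussian.
// Bp: T x (N*N) matrix, column (i*N + j) holds the density of frame t given
// the transition i -> j (i = j columns equal the plain state density; the
// first frame uses its i = j column).
// [[Rcpp::export]]
List hmm_forward_backward_pair(NumericMatrix Bp, NumericMatrix A,
                               NumericVector pi) {
  int T = Bp.nrow(), N = A.nrow();
  NumericMatrix alpha(T, N), beta(T, N);
  std::vector<double> c(T);
  double s = 0.0;
  for (int j = 0; j < N; ++j) {
    alpha(0, j) = pi[j] * Bp(0, j * N + j);
    s += alpha(0, j);
  }
  if (s <= 0) s = TINY;
  c[0] = s;
  for (int j = 0; j < N; ++j) alpha(0, j) /= s;
  for (int t = 1; t < T; ++t) {
    s = 0.0;
    for (int j = 0; j < N; ++j) {
      double a = 0.0;
      for (int i = 0; i < N; ++i)
        a += alpha(t - 1, i) * A(i, j) * Bp(t, i * N + j);
      alpha(t, j) = a;
      s += a;
    }
    if (s <= 0) s = TINY;
    c[t] = s;
    for (int j = 0; j < N; ++j) alpha(t, j) /= s;
  }
  for (int j = 0; j < N; ++j) beta(T - 1, j) = 1.0;
  for (int t = T - 2; t >= 0; --t)
    for (int i = 0; i < N; ++i) {
      double b = 0.0;
      for (int j = 0; j < N; ++j)
        b += A(i, j) * Bp(t + 1, i * N + j) * beta(t + 1, j);
      beta(t, i) = b / c[t + 1];
    }
  double loglik = 0.0;
  for (int t = 0; t < T; ++t) loglik += std::log(c[t]);
  NumericMatrix gamma(T, N);
  for (int t = 0; t < T; ++t) {
    double g = 0.0;
    for (int j = 0; j < N; ++j) { gamma(t, j) = alpha(t, j) * beta(t, j); g += gamma(t, j); }
    if (g > 0) for (int j = 0; j < N; ++j) gamma(t, j) /= g;
  }
  NumericMatrix xi_sum(N, N);
  for (int t = 0; t < T - 1; ++t)
    for (int i = 0; i < N; ++i) {
      if (alpha(t, i) <= 0) continue;
      for (int j = 0; j < N; ++j) {
        if (A(i, j) <= 0) continue;
        xi_sum(i, j) += alpha(t, i) * A(i, j) * Bp(t + 1, i * N + j) *
          beta(t + 1, j) / c[t + 1];
      }
    }
  return List::create(_["loglik"] = loglik, _["gamma"] = gamma,
                      _["xi_sum"] = xi_sum);
}

// Log-likelihood only, pair-emission variant.
// [[Rcpp::export]]
double hmm_loglik_pair(NumericMatrix Bp, NumericMatrix A, NumericVector pi) {
  int T = Bp.nrow(), N = A.nrow();
  std::vector<double> prev(N), cur(N);
  double loglik = 0.0, s = 0.0;
  for (int j = 0; j < N; ++j) { prev[j] = pi[j] * Bp(0, j * N + j); s += prev[j]; }
  if (s <= 0) s = TINY;
  loglik += std::log(s);
  for (int j = 0; j < N; ++j) prev[j] /= s;
  for (int t = 1; t < T; ++t) {
    s = 0.0;
    for (int j = 0; j < N; ++j) {
      double a = 0.0;
      for (int i = 0; i < N; ++i) a += prev[i] * A(i, j) * Bp(t, i * N + j);
      cur[j] = a;
      s += cur[j];
    }
    if (s <= 0) s = TINY;
    loglik += std::log(s);
    for (int j = 0; j < N; ++j) prev[j] = cur[j] / s;
  }
  return loglik;
}

// Scaled forward pass only: log-likelihood of one trace.
// [[Rcpp::export]]
double hmm_loglik(NumericMatrix B, NumericMatrix A, NumericVector pi) {
  int T = B.nrow(), N = B.ncol();
  std::vector<double> prev(N), cur(N);
  double loglik = 0.0, s = 0.0;
  for (int j = 0; j < N; ++j) { prev[j] = pi[j] * B(0, j); s += prev[j]; }
  if (s <= 0) s = TINY;
  loglik += std::log(s);
  for (int j = 0; j < N; ++j) prev[j] /= s;
  for (int t = 1; t < T; ++t) {
    s = 0.0;
    for (int j = 0; j < N; ++j) {
      double a = 0.0;
      for (int i = 0; i < N; ++i) a += prev[i] * A(i, j);
      cur[j] = a * B(t, j);
      s += cur[j];
    }
    if (s <= 0) s = TINY;
    loglik += std::log(s);
    for (int j = 0; j < N; ++j) prev[j] = cur[j] / s;
  }
  return loglik;
}

// Viterbi decoding in log space; ties broken toward the lower state index
// (strict > comparison while scanning ascending indices). Returns the
// 0-based most likely path and its joint log-probability.
// [[Rcpp::export]]
List hmm_viterbi(NumericMatrix logB, NumericMatrix logA,
                 NumericVector logpi) {
  int T = logB.nrow(), N = logB.ncol();
  NumericMatrix delta(T, N);
  IntegerMatrix psi(T, N);
  for (int j = 0; j < N; ++j) delta(0, j) = logpi[j] + logB(0, j);
  for (int t = 1; t < T; ++t)
    for (int j = 0; j < N; ++j) {
      double best = NEG_INF;
      int arg = 0;
      for (int i = 0; i < N; ++i) {
        double v = delta(t - 1, i) + logA(i, j);
        if (v > best) { best = v; arg = i; }
      }
      delta(t, j) = best + logB(t, j);
      psi(t, j) = arg;
    }
  double best = NEG_INF;
  int arg = 0;
  for (int j = 0; j < N; ++j)
    if (delta(T - 1, j) > best) { best = delta(T - 1, j); arg = j; }
  IntegerVector path(T);
  path[T - 1] = arg;
  for (int t = T - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);
  return List::create(_["path"] = path, _["logprob"] = best);
}
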