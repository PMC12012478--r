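#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward for a Gaussian-emission HMM.
// x: observations; mu, sd: per-state emission parameters; A: transition
// matrix (rows sum to 1); pi: initial distribution.
// Returns log-likelihood, posterior state probabilities gamma (T x K) and
// summed transition posteriors xi (K x K).
// [[Rcpp::export]]
List hmm_forward_backward(NumericVector x, NumericVector mu,
                          NumericVector sd, NumericMatrix A,
                          NumericVector pi) {
  const int T = x.size(), K = mu.size();
  NumericMatrix B(T, K);      // emission densities
  for (int k = 0; k < K; ++k) {
    const double inv = 1.0 / sd[k];
    const double norm = inv * 0.3989422804014327;
    for (int t = 0; t < T; ++t) {
      const double z = (x[t] - mu[k]) * inv;
      double b = norm * std::exp(-0.5 * z * z);
      B(t, k) = (b < 1e-300) ? 1e-300 : b;
    }
  }
  NumericMatrix alpha(T, K), beta(T, K);
  NumericVector c(T);
  double ll = 0.0;
  // forward
  double s = 0.0;
  for (int k = 0; k < K; ++k) { alpha(0, k) = pi[k] * B(0, k); s += alpha(0, k); }
  c[0] = s;
  for (int k = 0; k < K; ++k) alpha(0, k) /= s;
  ll += std::log(s);
  for (int t = 1; t < T; ++t) {
    s = 0.0;
    for (int k = 0; k < K; ++k) {
      double a = 0.0;
      for (int j = 0; j < K; ++j) a += alpha(t - 1, j) * A(j, k);
      a *= B(t, k);
      alpha(t, k) = a;
      s += a;
    }
    c[t] = s;
    for (int k = 0; k < K; ++k) alpha(t, k) /= s;
    ll += std::log(s);
  }
  // backward
  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int j = 0; j < K; ++j) {
      double b = 0.0;
      for (int k = 0; k < K; ++k) b += A(j, k) * B(t + 1, k) * beta(t + 1, k);
      beta(t, j) = b / c[t + 1];
    }
  }
  NumericMatrix gamma(T, K);
  for (int t = 0; t < T; ++t) {
    double g = 0.0;
    for (int k = 0; k < K; ++k) { gamma(t, k) = alpha(t, k) * beta(t, k); g += gamma(t, k); }
    for (int k = 0; k < K; ++k) gamma(t, k) /= g;
  }
  NumericMatrix xi(K, K);
  for (int t = 0; t < T - 1; ++t) {
    for (int j = 0; j < K; ++j) {
      const double aj = alpha(t, j);
      for (int k = 0; k < K; ++k) {
        xi(j, k) += aj * A(j, k) * B(t + 1, k) * beta(t + 1, k) / c[t + 1];
      }
    }
  }
  return List::create(_["loglik"] = ll, _["gamma"] = gamma, _["xi"] = xi);
}

// Viterbi decoding; ties broken toward the lowest state index.
// [[Rcpp::export]]
IntegerVector hmm_viterbi(NumericVector x, NumericVector mu,
                          NumericVector sd, NumericMatrix A,
                          NumericVector pi) {
  const int T = x.size(), K = mu.size();
  NumericMatrix logB(T, K);
  for (int k = 0; k < K; ++k) {
    const double inv = 1.0 / sd[k];
    const double lnorm = -std::log(sd[k]) - 0.9189385332046727;
    for (int t = 0; t < T; ++t) {
      const double z = (x[t] - mu[k]) * inv;
      logB(t, k) = lnorm - 0.5 * z * z;
    }
  }
  NumericMatrix logA(K, K);
  for (int j = 0; j < K; ++j)
    for (int k = 0; k < K; ++k)
      logA(j, k) = (A(j, k) > 0) ? std::log(A(j, k)) : -1e300;
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);
  for (int k = 0; k < K; ++k)
    delta(0, k) = ((pi[k] > 0) ? std::log(pi[k]) : -1e300) + logB(0, k);
  for (int t = 1; t < T; ++t) {
    for (int k = 0; k < K; ++k) {
      double best = delta(t - 1, 0) + logA(0, k);
      int arg = 0;
      for (int j = 1; j < K; ++j) {
        const double v = delta(t - 1, j) + logA(j, k);
        if (v > best) { best = v; arg = j; }   // strict: lowest index wins ties
      }
      delta(t, k) = best + logB(t, k);
      psi(t, k) = arg;
    }
  }
  IntegerVector path(T);
  double best = delta(T - 1, 0);
  int arg = 0;
  for (int k = 1; k < K; ++k)
    if (delta(T - 1, k) > best) { best = delta(T - 1, k); arg = k; }
  path[T - 1] = arg;
  for (int t = T - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);
  return path + 1;  // 1-based state indices
}
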