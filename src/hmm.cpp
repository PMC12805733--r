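#include <Rcpp.h>
using namespace Rcpp;

// Forward-backward smoothing for a 2-state HMM over independent bursts.
// emis: T x 2 matrix of emission probabilities P(obs_t | state).
// burst: integer vector length T; a new burst starts where burst changes.
// Phi: 2x2 transition matrix (rows: from). pi0: initial distribution applied
// at the start of every burst.
// Returns list(gamma = T x 2 smoothed marginals, loglik).
// [[Rcpp::export]]
List hmm_forward_backward(NumericMatrix emis, IntegerVector burst,
                          NumericMatrix Phi, NumericVector pi0) {
  int T = emis.nrow();
  NumericMatrix alpha(T, 2), beta(T, 2), gamma(T, 2);
  NumericVector cvec(T);
  double loglik = 0.0;
  for (int t = 0; t < T; ++t) {
    double a0, a1;
    if (t == 0 || burst[t] != burst[t - 1]) {
      a0 = pi0[0] * emis(t, 0);
      a1 = pi0[1] * emis(t, 1);
    } else {
      a0 = (alpha(t - 1, 0) * Phi(0, 0) + alpha(t - 1, 1) * Phi(1, 0)) * emis(t, 0);
      a1 = (alpha(t - 1, 0) * Phi(0, 1) + alpha(t - 1, 1) * Phi(1, 1)) * emis(t, 1);
    }
    double c = a0 + a1;
    if (c <= 0.0) { a0 = 1e-300; a1 = 1e-300; c = 2e-300; }
    alpha(t, 0) = a0 / c;
    alpha(t, 1) = a1 / c;
    cvec[t] = c;
    loglik += std::log(c);
  }
  for (int t = T - 1; t >= 0; --t) {
    double b0, b1;
    if (t == T - 1 || burst[t + 1] != burst[t]) {
      b0 = 1.0; b1 = 1.0;
    } else {
      b0 = Phi(0, 0) * emis(t + 1, 0) * beta(t + 1, 0) +
           Phi(0, 1) * emis(t + 1, 1) * beta(t + 1, 1);
      b1 = Phi(1, 0) * emis(t + 1, 0) * beta(t + 1, 0) +
           Phi(1, 1) * emis(t + 1, 1) * beta(t + 1, 1);
      double m = std::max(b0, b1);
      if (m <= 0.0) { b0 = 1.0; b1 = 1.0; } else { b0 /= m; b1 /= m; }
    }
    beta(t, 0) = b0;
    beta(t, 1) = b1;
    double g0 = alpha(t, 0) * b0, g1 = alpha(t, 1) * b1;
    double s = g0 + g1;
    gamma(t, 0) = g0 / s;
    gamma(t, 1) = g1 / s;
  }
  return List::create(_["gamma"] = gamma, _["loglik"] = loglik);
}

// Forward-filter backward-sample draw of the latent state sequence (FFBS).
// Uses R's RNG so results are reproducible under set.seed().
// Returns integer vector of states in {1, 2}.
// [[Rcpp::export]]
IntegerVector hmm_ffbs(NumericMatrix emis, IntegerVector burst,
                       NumericMatrix Phi, NumericVector pi0) {
  int T = emis.nrow();
  NumericMatrix alpha(T, 2);
  for (int t = 0; t < T; ++t) {
    double a0, a1;
    if (t == 0 || burst[t] != burst[t - 1]) {
      a0 = pi0[0] * emis(t, 0);
      a1 = pi0[1] * emis(t, 1);
    } else {
      a0 = (alpha(t - 1, 0) * Phi(0, 0) + alpha(t - 1, 1) * Phi(1, 0)) * emis(t, 0);
      a1 = (alpha(t - 1, 0) * Phi(0, 1) + alpha(t - 1, 1) * Phi(1, 1)) * emis(t, 1);
    }
    double c = a0 + a1;
    if (c <= 0.0) { a0 = 0.5; a1 = 0.5; c = 1.0; }
    alpha(t, 0) = a0 / c;
    alpha(t, 1) = a1 / c;
  }
  // RNG scope is provided by the Rcpp attributes wrapper
  IntegerVector z(T);
  for (int t = T - 1; t >= 0; --t) {
    double p1; // probability of state 1 (index 0)
    if (t == T - 1 || burst[t + 1] != burst[t]) {
      p1 = alpha(t, 0);
    } else {
      int znext = z[t + 1] - 1;
      double w0 = alpha(t, 0) * Phi(0, znext);
      double w1 = alpha(t, 1) * Phi(1, znext);
      double s = w0 + w1;
      p1 = (s > 0.0) ? w0 / s : 0.5;
    }
    z[t] = (unif_rand() < p1) ? 1 : 2;
  }
  return z;
}
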