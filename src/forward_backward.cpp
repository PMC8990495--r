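// Scaled forward-backward and forward-only recursions for Gaussian-emission
// HMMs over many short fixation sequences. Emission log-weights arrive
// precomputed (N x K, rows in sequence order); sequences are processed
// independently, each rescaled per fixation for numerical stability.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export(name = ".fb_cpp")]]
List fb_cpp(NumericVector pi0, NumericMatrix A, NumericMatrix logB,
            IntegerVector lens, NumericVector w) {
  const int K = pi0.size();
  const int S = lens.size();
  const int N = logB.nrow();
  NumericMatrix gamma(N, K);
  NumericMatrix xi(K, K);
  NumericMatrix gamma1(S, K);
  NumericVector logz(S);

  std::vector<double> B, alpha, beta(K), betanew(K), cs;
  int start = 0;
  for (int s = 0; s < S; ++s) {
    const int T = lens[s];
    const double ws = w[s];
    B.assign((size_t)T * K, 0.0);
    alpha.assign((size_t)T * K, 0.0);
    cs.assign(T, 0.0);
    double scale_total = 0.0;
    for (int t = 0; t < T; ++t) {
      double m = R_NegInf;
      for (int k = 0; k < K; ++k)
        m = std::max(m, logB(start + t, k));
      if (!std::isfinite(m)) m = 0.0;
      scale_total += m;
      for (int k = 0; k < K; ++k)
        B[(size_t)t * K + k] = std::exp(logB(start + t, k) - m);
    }
    // forward
    double c0 = 0.0;
    for (int k = 0; k < K; ++k) {
      alpha[k] = pi0[k] * B[k];
      c0 += alpha[k];
    }
    cs[0] = c0;
    for (int k = 0; k < K; ++k) alpha[k] /= c0;
    for (int t = 1; t < T; ++t) {
      double ct = 0.0;
      for (int j = 0; j < K; ++j) {
        double acc = 0.0;
        for (int i = 0; i < K; ++i)
          acc += alpha[(size_t)(t - 1) * K + i] * A(i, j);
        const double v = acc * B[(size_t)t * K + j];
        alpha[(size_t)t * K + j] = v;
        ct += v;
      }
      cs[t] = ct;
      for (int j = 0; j < K; ++j) alpha[(size_t)t * K + j] /= ct;
    }
    double lz = scale_total;
    for (int t = 0; t < T; ++t) lz += std::log(cs[t]);
    logz[s] = lz;
    // backward, accumulating gamma and weighted xi
    for (int k = 0; k < K; ++k) {
      beta[k] = 1.0;
      gamma(start + T - 1, k) = alpha[(size_t)(T - 1) * K + k];
    }
    for (int t = T - 2; t >= 0; --t) {
      // wB[j] = B[t+1, j] * beta[j] / c[t+1]
      double gsum = 0.0;
      for (int i = 0; i < K; ++i) {
        double acc = 0.0;
        for (int j = 0; j < K; ++j) {
          const double wBj = B[(size_t)(t + 1) * K + j] * beta[j] / cs[t + 1];
          acc += A(i, j) * wBj;
          xi(i, j) += ws * alpha[(size_t)t * K + i] * A(i, j) * wBj;
        }
        betanew[i] = acc;
        gamma(start + t, i) = alpha[(size_t)t * K + i] * acc;
        gsum += gamma(start + t, i);
      }
      for (int i = 0; i < K; ++i) {
        gamma(start + t, i) /= gsum;
        beta[i] = betanew[i];
      }
    }
    for (int k = 0; k < K; ++k) gamma1(s, k) = gamma(start, k);
    start += T;
  }
  return List::create(_["gamma"] = gamma, _["xi"] = xi,
                      _["gamma1"] = gamma1, _["logz"] = logz);
}

// [[Rcpp::export(name = ".forward_logz_cpp")]]
NumericVector forward_logz_cpp(NumericVector pi0, NumericMatrix A,
                               NumericMatrix logB, IntegerVector lens) {
  const int K = pi0.size();
  const int S = lens.size();
  NumericVector logz(S);
  std::vector<double> alpha(K), anew(K), B(K);
  int start = 0;
  for (int s = 0; s < S; ++s) {
    const int T = lens[s];
    double lz = 0.0;
    for (int t = 0; t < T; ++t) {
      double m = R_NegInf;
      for (int k = 0; k < K; ++k)
        m = std::max(m, logB(start + t, k));
      if (!std::isfinite(m)) m = 0.0;
      lz += m;
      for (int k = 0; k < K; ++k)
        B[k] = std::exp(logB(start + t, k) - m);
      double ct = 0.0;
      if (t == 0) {
        for (int k = 0; k < K; ++k) {
          anew[k] = pi0[k] * B[k];
          ct += anew[k];
        }
      } else {
        for (int j = 0; j < K; ++j) {
          double acc = 0.0;
          for (int i = 0; i < K; ++i) acc += alpha[i] * A(i, j);
          anew[j] = acc * B[j];
          ct += anew[j];
        }
      }
      for (int k = 0; k < K; ++k) alpha[k] = anew[k] / ct;
      lz += std::log(ct);
    }
    logz[s] = lz;
    start += T;
  }
  return logz;
}
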