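#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Univariate Gaussian HMM recursions with per-step scaling.
// Row-major (T x K) work buffers keep the inner K-loops contiguous.
// States are 0-based internally; R-facing wrappers return 1-based paths.

static std::vector<double> gauss_dens(const NumericVector& obs,
                                      const NumericVector& mu,
                                      const NumericVector& sigma) {
  const int T = obs.size(), K = mu.size();
  std::vector<double> dens((size_t)T * K);
  for (int k = 0; k < K; ++k) {
    const double s = sigma[k], m = mu[k];
    const double c = 1.0 / (s * std::sqrt(2.0 * M_PI));
    const double inv2s2 = 0.5 / (s * s);
    for (int t = 0; t < T; ++t) {
      const double d = obs[t] - m;
      dens[(size_t)t * K + k] = c * std::exp(-d * d * inv2s2);
    }
  }
  return dens;
}

// [[Rcpp::export(name = ".hmm_forward_cpp")]]
double hmm_forward_cpp(NumericVector obs, NumericVector pi, NumericMatrix A,
                       NumericVector mu, NumericVector sigma) {
  const int T = obs.size(), K = mu.size();
  std::vector<double> dens = gauss_dens(obs, mu, sigma);
  std::vector<double> Arm((size_t)K * K);  // row-major transition matrix
  for (int j = 0; j < K; ++j)
    for (int k = 0; k < K; ++k) Arm[(size_t)j * K + k] = A(j, k);

  std::vector<double> alpha(K), anew(K);
  double loglik = 0.0, c = 0.0;
  for (int k = 0; k < K; ++k) { alpha[k] = pi[k] * dens[k]; c += alpha[k]; }
  if (c <= 0.0) return R_NegInf;
  for (int k = 0; k < K; ++k) alpha[k] /= c;
  loglik += std::log(c);

  for (int t = 1; t < T; ++t) {
    const double* dt = &dens[(size_t)t * K];
    c = 0.0;
    for (int k = 0; k < K; ++k) anew[k] = 0.0;
    for (int j = 0; j < K; ++j) {
      const double aj = alpha[j];
      const double* Aj = &Arm[(size_t)j * K];
      for (int k = 0; k < K; ++k) anew[k] += aj * Aj[k];
    }
    for (int k = 0; k < K; ++k) { anew[k] *= dt[k]; c += anew[k]; }
    if (c <= 0.0) return R_NegInf;
    for (int k = 0; k < K; ++k) alpha[k] = anew[k] / c;
    loglik += std::log(c);
  }
  return loglik;
}

// E-step quantities: loglik, state posteriors gamma (T x K), and the summed
// transition posteriors xi (K x K) needed by the Baum-Welch M-step.
// [[Rcpp::export(name = ".hmm_forward_backward_cpp")]]
List hmm_forward_backward_cpp(NumericVector obs, NumericVector pi,
                              NumericMatrix A, NumericVector mu,
                              NumericVector sigma) {
  const int T = obs.size(), K = mu.size();
  std::vector<double> dens = gauss_dens(obs, mu, sigma);
  std::vector<double> Arm((size_t)K * K);
  for (int j = 0; j < K; ++j)
    for (int k = 0; k < K; ++k) Arm[(size_t)j * K + k] = A(j, k);

  std::vector<double> alpha((size_t)T * K), beta((size_t)T * K), cvec(T);
  double loglik = 0.0, c = 0.0;
  for (int k = 0; k < K; ++k) { alpha[k] = pi[k] * dens[k]; c += alpha[k]; }
  if (c <= 0.0) stop("forward pass underflow: zero likelihood at t = 1");
  for (int k = 0; k < K; ++k) alpha[k] /= c;
  cvec[0] = c; loglik += std::log(c);

  std::vector<double> anew(K);
  for (int t = 1; t < T; ++t) {
    const double* ap = &alpha[(size_t)(t - 1) * K];
    const double* dt = &dens[(size_t)t * K];
    double* at = &alpha[(size_t)t * K];
    c = 0.0;
    for (int k = 0; k < K; ++k) anew[k] = 0.0;
    for (int j = 0; j < K; ++j) {
      const double aj = ap[j];
      const double* Aj = &Arm[(size_t)j * K];
      for (int k = 0; k < K; ++k) anew[k] += aj * Aj[k];
    }
    for (int k = 0; k < K; ++k) { at[k] = anew[k] * dt[k]; c += at[k]; }
    if (c <= 0.0) stop("forward pass underflow: zero likelihood at t = %d", t + 1);
    for (int k = 0; k < K; ++k) at[k] /= c;
    cvec[t] = c; loglik += std::log(c);
  }

  for (int k = 0; k < K; ++k) beta[(size_t)(T - 1) * K + k] = 1.0;
  std::vector<double> bd(K);
  for (int t = T - 2; t >= 0; --t) {
    const double* bn = &beta[(size_t)(t + 1) * K];
    const double* dn = &dens[(size_t)(t + 1) * K];
    double* bt = &beta[(size_t)t * K];
    const double invc = 1.0 / cvec[t + 1];
    for (int k = 0; k < K; ++k) bd[k] = dn[k] * bn[k];
    for (int j = 0; j < K; ++j) {
      const double* Aj = &Arm[(size_t)j * K];
      double s = 0.0;
      for (int k = 0; k < K; ++k) s += Aj[k] * bd[k];
      bt[j] = s * invc;
    }
  }

  NumericMatrix gamma(T, K);
  for (int t = 0; t < T; ++t) {
    const double* at = &alpha[(size_t)t * K];
    const double* bt = &beta[(size_t)t * K];
    double s = 0.0;
    for (int k = 0; k < K; ++k) s += at[k] * bt[k];
    for (int k = 0; k < K; ++k) gamma(t, k) = at[k] * bt[k] / s;
  }

  std::vector<double> xi((size_t)K * K, 0.0);
  for (int t = 0; t < T - 1; ++t) {
    const double* at = &alpha[(size_t)t * K];
    const double* bn = &beta[(size_t)(t + 1) * K];
    const double* dn = &dens[(size_t)(t + 1) * K];
    const double invc = 1.0 / cvec[t + 1];
    for (int k = 0; k < K; ++k) bd[k] = dn[k] * bn[k] * invc;
    for (int j = 0; j < K; ++j) {
      const double aj = at[j];
      const double* Aj = &Arm[(size_t)j * K];
      double* xj = &xi[(size_t)j * K];
      for (int k = 0; k < K; ++k) xj[k] += aj * Aj[k] * bd[k];
    }
  }
  NumericMatrix xi_out(K, K);
  for (int j = 0; j < K; ++j)
    for (int k = 0; k < K; ++k) xi_out(j, k) = xi[(size_t)j * K + k];

  return List::create(_["loglik"] = loglik, _["gamma"] = gamma,
                      _["xi_sum"] = xi_out);
}

// Most probable state path in log space; ties broken toward the lower index
// (strict > when comparing candidates scanned in increasing j).
// [[Rcpp::export(name = ".hmm_viterbi_cpp")]]
IntegerVector hmm_viterbi_cpp(NumericVector obs, NumericVector pi,
                              NumericMatrix A, NumericVector mu,
                              NumericVector sigma) {
  const int T = obs.size(), K = mu.size();
  std::vector<double> logdens((size_t)T * K);
  for (int k = 0; k < K; ++k) {
    const double s = sigma[k], m = mu[k];
    const double lc = -std::log(s) - 0.5 * std::log(2.0 * M_PI);
    const double inv2s2 = 0.5 / (s * s);
    for (int t = 0; t < T; ++t) {
      const double d = obs[t] - m;
      logdens[(size_t)t * K + k] = lc - d * d * inv2s2;
    }
  }
  std::vector<double> logA((size_t)K * K);
  for (int j = 0; j < K; ++j)
    for (int k = 0; k < K; ++k) logA[(size_t)j * K + k] = std::log(A(j, k));

  std::vector<double> prev(K), cur(K);
  std::vector<int> psi((size_t)T * K);
  for (int k = 0; k < K; ++k) prev[k] = std::log(pi[k]) + logdens[k];
  for (int t = 1; t < T; ++t) {
    const double* dt = &logdens[(size_t)t * K];
    int* pt = &psi[(size_t)t * K];
    for (int k = 0; k < K; ++k) {
      double best = R_NegInf; int arg = 0;
      for (int j = 0; j < K; ++j) {
        const double cand = prev[j] + logA[(size_t)j * K + k];
        if (cand > best) { best = cand; arg = j; }
      }
      cur[k] = best + dt[k];
      pt[k] = arg;
    }
    std::swap(prev, cur);
  }

  IntegerVector path(T);
  double best = R_NegInf; int arg = 0;
  for (int k = 0; k < K; ++k)
    if (prev[k] > best) { best = prev[k]; arg = k; }
  path[T - 1] = arg;
  for (int t = T - 2; t >= 0; --t)
    path[t] = psi[(size_t)(t + 1) * K + path[t + 1]];
  for (int t = 0; t < T; ++t) path[t] += 1;
  return path;
}
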