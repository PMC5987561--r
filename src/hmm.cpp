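#include <Rcpp.h>
using namespace Rcpp;

// log-sum-exp of a small vector
static inline double lse(const double *x, int k) {
  double m = x[0];
  for (int i = 1; i < k; ++i) if (x[i] > m) m = x[i];
  if (!R_FINITE(m)) return m;
  double s = 0.0;
  for (int i = 0; i < k; ++i) s += std::exp(x[i] - m);
  return m + std::log(s);
}

// Forward-backward for one chain of a heterogeneous HMM.
// logdens: n x K log emission densities; loga: K x K x (n-1) log transition
// matrices (rows = from); logpi: initial log probabilities.
// Returns posteriors (gamma, n x K), expected transition counts per step
// (xi, K x K x (n-1)) and the log-likelihood.
// [[Rcpp::export]]
List hmm_forward_backward_cpp(NumericMatrix logdens, NumericVector loga,
                              NumericVector logpi) {
  const int n = logdens.nrow(), K = logdens.ncol();
  NumericMatrix alpha(n, K), beta(n, K), gamma(n, K);
  std::vector<double> tmp(K);
  const double *A = loga.begin();

  for (int j = 0; j < K; ++j) alpha(0, j) = logpi[j] + logdens(0, j);
  for (int t = 1; t < n; ++t) {
    const double *At = A + (size_t)(t - 1) * K * K; // column-major K x K
    for (int k = 0; k < K; ++k) {
      for (int j = 0; j < K; ++j) tmp[j] = alpha(t - 1, j) + At[j + k * K];
      alpha(t, k) = lse(tmp.data(), K) + logdens(t, k);
    }
  }
  for (int j = 0; j < K; ++j) tmp[j] = alpha(n - 1, j);
  const double loglik = lse(tmp.data(), K);

  for (int j = 0; j < K; ++j) beta(n - 1, j) = 0.0;
  for (int t = n - 2; t >= 0; --t) {
    const double *At = A + (size_t)t * K * K;
    for (int j = 0; j < K; ++j) {
      for (int k = 0; k < K; ++k)
        tmp[k] = At[j + k * K] + logdens(t + 1, k) + beta(t + 1, k);
      beta(t, j) = lse(tmp.data(), K);
    }
  }
  for (int t = 0; t < n; ++t) {
    for (int j = 0; j < K; ++j) tmp[j] = alpha(t, j) + beta(t, j);
    double z = lse(tmp.data(), K);
    for (int j = 0; j < K; ++j) gamma(t, j) = std::exp(tmp[j] - z);
  }

  NumericVector xi(std::max(0, (n - 1)) * K * K);
  double *X = xi.begin();
  for (int t = 0; t < n - 1; ++t) {
    const double *At = A + (size_t)t * K * K;
    double *Xt = X + (size_t)t * K * K;
    for (int k = 0; k < K; ++k)
      for (int j = 0; j < K; ++j)
        Xt[j + k * K] = std::exp(alpha(t, j) + At[j + k * K] +
                                 logdens(t + 1, k) + beta(t + 1, k) - loglik);
  }
  if (n > 1) xi.attr("dim") = IntegerVector::create(K, K, n - 1);

  return List::create(_["gamma"] = gamma, _["xi"] = xi,
                      _["loglik"] = loglik);
}

// Viterbi decoding for one chain; ties broken toward the lower state index.
// Returns the 1-based most probable path and its log-probability.
// [[Rcpp::export]]
List hmm_viterbi_cpp(NumericMatrix logdens, NumericVector loga,
                     NumericVector logpi) {
  const int n = logdens.nrow(), K = logdens.ncol();
  NumericMatrix delta(n, K);
  IntegerMatrix psi(n, K);
  const double *A = loga.begin();

  for (int j = 0; j < K; ++j) delta(0, j) = logpi[j] + logdens(0, j);
  for (int t = 1; t < n; ++t) {
    const double *At = A + (size_t)(t - 1) * K * K;
    for (int k = 0; k < K; ++k) {
      int arg = 0;
      double best = delta(t - 1, 0) + At[0 + k * K];
      for (int j = 1; j < K; ++j) {
        double s = delta(t - 1, j) + At[j + k * K];
        if (s > best) { best = s; arg = j; } // strict: ties keep lower j
      }
      delta(t, k) = best + logdens(t, k);
      psi(t, k) = arg;
    }
  }
  IntegerVector path(n);
  int arg = 0;
  double best = delta(n - 1, 0);
  for (int j = 1; j < K; ++j)
    if (delta(n - 1, j) > best) { best = delta(n - 1, j); arg = j; }
  path[n - 1] = arg + 1;
  for (int t = n - 2; t >= 0; --t) {
    arg = psi(t + 1, arg);
    path[t] = arg + 1;
  }
  return List::create(_["path"] = path, _["logprob"] = best);
}
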