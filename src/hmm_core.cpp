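#include <Rcpp.h>
using namespace Rcpp;

// Log-space forward-backward for one chromosome.
// logE: T x K matrix of per-bin log emission probabilities
// logA: K x K log transition matrix, logPi: length-K log initial probs.
// Returns loglik, gamma (T x K posteriors) and xi_sum (K x K expected
// transition counts), all needed for one Baum-Welch E-step.

static double logsumexp(const std::vector<double>& v) {
  double m = R_NegInf;
  for (double x : v) if (x > m) m = x;
  if (!R_finite(m)) return R_NegInf;
  double s = 0.0;
  for (double x : v) s += std::exp(x - m);
  return m + std::log(s);
}

// [[Rcpp::export(name = ".fb_chrom")]]
List fb_chrom(NumericMatrix logE, NumericMatrix logA, NumericVector logPi) {
  const int T = logE.nrow(), K = logE.ncol();
  NumericMatrix alpha(T, K), beta(T, K), gamma(T, K);
  std::vector<double> tmp(K);

  for (int k = 0; k < K; ++k) alpha(0, k) = logPi[k] + logE(0, k);
  for (int t = 1; t < T; ++t) {
    for (int k = 0; k < K; ++k) {
      for (int j = 0; j < K; ++j) tmp[j] = alpha(t - 1, j) + logA(j, k);
      alpha(t, k) = logsumexp(tmp) + logE(t, k);
    }
  }
  for (int k = 0; k < K; ++k) tmp[k] = alpha(T - 1, k);
  const double ll = logsumexp(tmp);

  for (int k = 0; k < K; ++k) beta(T - 1, k) = 0.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int k = 0; k < K; ++k) {
      for (int j = 0; j < K; ++j)
        tmp[j] = logA(k, j) + logE(t + 1, j) + beta(t + 1, j);
      beta(t, k) = logsumexp(tmp);
    }
  }

  for (int t = 0; t < T; ++t) {
    for (int k = 0; k < K; ++k) tmp[k] = alpha(t, k) + beta(t, k) - ll;
    double norm = logsumexp(tmp);
    for (int k = 0; k < K; ++k) gamma(t, k) = std::exp(tmp[k] - norm);
  }

  NumericMatrix xi(K, K);
  std::fill(xi.begin(), xi.end(), 0.0);
  for (int t = 0; t < T - 1; ++t) {
    // normalise xi_t before accumulating
    double m = R_NegInf;
    NumericMatrix lx(K, K);
    for (int j = 0; j < K; ++j)
      for (int k = 0; k < K; ++k) {
        lx(j, k) = alpha(t, j) + logA(j, k) + logE(t + 1, k) + beta(t + 1, k);
        if (lx(j, k) > m) m = lx(j, k);
      }
    if (!R_finite(m)) continue;
    double s = 0.0;
    for (int j = 0; j < K; ++j)
      for (int k = 0; k < K; ++k) s += std::exp(lx(j, k) - m);
    for (int j = 0; j < K; ++j)
      for (int k = 0; k < K; ++k) xi(j, k) += std::exp(lx(j, k) - m) / s;
  }

  return List::create(_["loglik"] = ll, _["gamma"] = gamma, _["xi_sum"] = xi);
}

// [[Rcpp::export(name = ".viterbi_chrom")]]
IntegerVector viterbi_chrom(NumericMatrix logE, NumericMatrix logA,
                            NumericVector logPi) {
  const int T = logE.nrow(), K = logE.ncol();
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);

  for (int k = 0; k < K; ++k) delta(0, k) = logPi[k] + logE(0, k);
  for (int t = 1; t < T; ++t) {
    for (int k = 0; k < K; ++k) {
      double best = R_NegInf;
      int arg = 0;
      for (int j = 0; j < K; ++j) {
        double v = delta(t - 1, j) + logA(j, k);
        if (v > best) { best = v; arg = j; }
      }
      delta(t, k) = best + logE(t, k);
      psi(t, k) = arg;
    }
  }
  IntegerVector path(T);
  double best = R_NegInf;
  for (int k = 0; k < K; ++k)
    if (delta(T - 1, k) > best) { best = delta(T - 1, k); path[T - 1] = k; }
  for (int t = T - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);
  for (int t = 0; t < T; ++t) path[t] += 1; // 1-based state index for R
  return path;
}
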