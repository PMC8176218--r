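#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Two-state Poisson-emission HMM for transcribed-segment calling.
// State 0 = background (low lambda), state 1 = transcribed (high lambda).
// EM in log space with scaling; Viterbi decode.  Counts are rounded
// non-negative coverage values.

static inline double logpois(double x, double lambda) {
  if (lambda <= 0) lambda = 1e-10;
  return x * std::log(lambda) - lambda - std::lgamma(x + 1.0);
}

// [[Rcpp::export(name = ".cpp_poisson_hmm")]]
List cpp_poisson_hmm(NumericVector x, int max_iter = 200,
                     double tol = 1e-6) {
  const int n = x.size();
  if (n == 0) return List::create(_["viterbi"] = IntegerVector(0));
  // init: lambdas from lower/upper halves of the positive values
  double mean_all = 0.0;
  for (int i = 0; i < n; ++i) mean_all += x[i];
  mean_all /= n;
  double lam0 = std::max(0.5 * mean_all, 1e-4);
  double lam1 = std::max(2.0 * mean_all + 1.0, lam0 * 4.0);
  double a00 = 0.999, a11 = 0.999;   // sticky transitions
  double pi1 = 0.5;
  std::vector<double> alpha0(n), alpha1(n), beta0(n), beta1(n), scale(n);
  double loglik_old = -1e300, loglik = 0.0;

  for (int iter = 0; iter < max_iter; ++iter) {
    // forward with scaling
    double e0 = std::exp(logpois(x[0], lam0));
    double e1 = std::exp(logpois(x[0], lam1));
    alpha0[0] = (1.0 - pi1) * e0;
    alpha1[0] = pi1 * e1;
    scale[0] = alpha0[0] + alpha1[0];
    if (scale[0] <= 0) scale[0] = 1e-300;
    alpha0[0] /= scale[0]; alpha1[0] /= scale[0];
    for (int t = 1; t < n; ++t) {
      e0 = std::exp(logpois(x[t], lam0));
      e1 = std::exp(logpois(x[t], lam1));
      alpha0[t] = (alpha0[t-1] * a00 + alpha1[t-1] * (1.0 - a11)) * e0;
      alpha1[t] = (alpha0[t-1] * (1.0 - a00) + alpha1[t-1] * a11) * e1;
      scale[t] = alpha0[t] + alpha1[t];
      if (scale[t] <= 0) scale[t] = 1e-300;
      alpha0[t] /= scale[t]; alpha1[t] /= scale[t];
    }
    loglik = 0.0;
    for (int t = 0; t < n; ++t) loglik += std::log(scale[t]);
    // backward
    beta0[n-1] = 1.0; beta1[n-1] = 1.0;
    for (int t = n - 2; t >= 0; --t) {
      e0 = std::exp(logpois(x[t+1], lam0));
      e1 = std::exp(logpois(x[t+1], lam1));
      beta0[t] = (a00 * e0 * beta0[t+1] + (1.0 - a00) * e1 * beta1[t+1]) /
        scale[t+1];
      beta1[t] = ((1.0 - a11) * e0 * beta0[t+1] + a11 * e1 * beta1[t+1]) /
        scale[t+1];
    }
    // expected counts
    double s0 = 0, s1 = 0, w0 = 0, w1 = 0;
    double n00 = 0, n01 = 0, n10 = 0, n11 = 0;
    for (int t = 0; t < n; ++t) {
      double g0 = alpha0[t] * beta0[t];
      double g1 = alpha1[t] * beta1[t];
      double gs = g0 + g1;
      if (gs <= 0) gs = 1e-300;
      g0 /= gs; g1 /= gs;
      w0 += g0; w1 += g1;
      s0 += g0 * x[t]; s1 += g1 * x[t];
      if (t < n - 1) {
        e0 = std::exp(logpois(x[t+1], lam0));
        e1 = std::exp(logpois(x[t+1], lam1));
        double x00 = alpha0[t] * a00 * e0 * beta0[t+1] / scale[t+1];
        double x01 = alpha0[t] * (1.0 - a00) * e1 * beta1[t+1] / scale[t+1];
        double x10 = alpha1[t] * (1.0 - a11) * e0 * beta0[t+1] / scale[t+1];
        double x11 = alpha1[t] * a11 * e1 * beta1[t+1] / scale[t+1];
        double xs = x00 + x01 + x10 + x11;
        if (xs <= 0) xs = 1e-300;
        n00 += x00 / xs; n01 += x01 / xs;
        n10 += x10 / xs; n11 += x11 / xs;
      }
    }
    double pi1_new = alpha1[0] * beta1[0] /
      (alpha0[0] * beta0[0] + alpha1[0] * beta1[0]);
    double lam0_new = (w0 > 0) ? s0 / w0 : lam0;
    double lam1_new = (w1 > 0) ? s1 / w1 : lam1;
    double a00_new = (n00 + n01 > 0) ? n00 / (n00 + n01) : a00;
    double a11_new = (n10 + n11 > 0) ? n11 / (n10 + n11) : a11;
    // keep state 1 the high-coverage state
    if (lam1_new < lam0_new) {
      std::swap(lam0_new, lam1_new);
      std::swap(a00_new, a11_new);
      pi1_new = 1.0 - pi1_new;
    }
    bool conv = std::fabs(loglik - loglik_old) < tol * (1.0 + std::fabs(loglik));
    lam0 = std::max(lam0_new, 1e-6);
    lam1 = std::max(lam1_new, lam0 + 1e-6);
    a00 = std::min(std::max(a00_new, 1e-9), 1.0 - 1e-9);
    a11 = std::min(std::max(a11_new, 1e-9), 1.0 - 1e-9);
    pi1 = std::min(std::max(pi1_new, 1e-9), 1.0 - 1e-9);
    loglik_old = loglik;
    if (conv && iter > 0) break;
  }

  // Viterbi in log space
  std::vector<double> d0(n), d1(n);
  std::vector<signed char> bp0(n), bp1(n);
  double la00 = std::log(a00), la01 = std::log(1.0 - a00);
  double la10 = std::log(1.0 - a11), la11 = std::log(a11);
  d0[0] = std::log(1.0 - pi1) + logpois(x[0], lam0);
  d1[0] = std::log(pi1) + logpois(x[0], lam1);
  for (int t = 1; t < n; ++t) {
    double c00 = d0[t-1] + la00, c10 = d1[t-1] + la10;
    if (c00 >= c10) { d0[t] = c00; bp0[t] = 0; }
    else { d0[t] = c10; bp0[t] = 1; }
    d0[t] += logpois(x[t], lam0);
    double c01 = d0[t-1] + la01, c11 = d1[t-1] + la11;
    if (c11 >= c01) { d1[t] = c11; bp1[t] = 1; }
    else { d1[t] = c01; bp1[t] = 0; }
    d1[t] += logpois(x[t], lam1);
  }
  IntegerVector path(n);
  int s = (d1[n-1] >= d0[n-1]) ? 1 : 0;
  path[n-1] = s;
  for (int t = n - 1; t > 0; --t) {
    s = (s == 0) ? bp0[t] : bp1[t];
    path[t-1] = s;
  }
  return List::create(_["viterbi"] = path,
                      _["lambda"] = NumericVector::create(lam0, lam1),
                      _["a00"] = a00, _["a11"] = a11,
                      _["loglik"] = loglik);
}
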