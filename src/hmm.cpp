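// Gaussian-emission HMM core: scaled forward/backward, Baum-Welch EM and
// Viterbi decoding. Scaling (per-sample normalisation with log-accumulated
// normalisers) gives the same numerical stability as log-space recursions
// at a fraction of the cost, which matters for megasample traces.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double dnorm_log(double x, double mean, double sd) {
  static const double LOG_SQRT_2PI = 0.9189385332046727;
  double z = (x - mean) / sd;
  return -0.5 * z * z - std::log(sd) - LOG_SQRT_2PI;
}

// Emission density matrix, scaled per sample to avoid underflow.
// Returns b[t][k] = exp(logB[t][k] - max_k logB[t][k]) and the per-sample max.
static void emissions(const NumericVector& x, const NumericVector& means,
                      const NumericVector& sds, std::vector<double>& b,
                      std::vector<double>& bmax) {
  const int T = x.size(), K = means.size();
  for (int t = 0; t < T; ++t) {
    double m = -INFINITY;
    for (int k = 0; k < K; ++k) {
      double l = dnorm_log(x[t], means[k], sds[k]);
      b[(size_t)t * K + k] = l;
      if (l > m) m = l;
    }
    bmax[t] = m;
    for (int k = 0; k < K; ++k)
      b[(size_t)t * K + k] = std::exp(b[(size_t)t * K + k] - m);
  }
}

// [[Rcpp::export(name = ".tk_forward_cpp")]]
double tk_forward_cpp(NumericVector x, NumericVector init, NumericMatrix trans,
                      NumericVector means, NumericVector sds) {
  const int T = x.size(), K = means.size();
  std::vector<double> b((size_t)T * K), bmax(T);
  emissions(x, means, sds, b, bmax);
  std::vector<double> alpha(K), tmp(K);
  double loglik = 0.0;
  for (int k = 0; k < K; ++k) alpha[k] = init[k] * b[k];
  double c = 0.0;
  for (int k = 0; k < K; ++k) c += alpha[k];
  if (c <= 0) return -INFINITY;
  for (int k = 0; k < K; ++k) alpha[k] /= c;
  loglik += std::log(c) + bmax[0];
  for (int t = 1; t < T; ++t) {
    for (int k = 0; k < K; ++k) {
      double s = 0.0;
      for (int j = 0; j < K; ++j) s += alpha[j] * trans(j, k);
      tmp[k] = s * b[(size_t)t * K + k];
    }
    c = 0.0;
    for (int k = 0; k < K; ++k) c += tmp[k];
    if (c <= 0) return -INFINITY;
    for (int k = 0; k < K; ++k) alpha[k] = tmp[k] / c;
    loglik += std::log(c) + bmax[t];
  }
  return loglik;
}

// One EM (Baum-Welch) sweep; returns updated parameters and the loglik of
// the *input* parameters.
// [[Rcpp::export(name = ".tk_em_step_cpp")]]
List tk_em_step_cpp(NumericVector x, NumericVector init, NumericMatrix trans,
                    NumericVector means, NumericVector sds) {
  const int T = x.size(), K = means.size();
  std::vector<double> b((size_t)T * K), bmax(T);
  emissions(x, means, sds, b, bmax);

  // scaled forward, storing alpha for the backward sweep
  std::vector<double> alpha((size_t)T * K);
  std::vector<double> scale(T);
  double loglik = 0.0;
  {
    double c = 0.0;
    for (int k = 0; k < K; ++k) {
      alpha[k] = init[k] * b[k];
      c += alpha[k];
    }
    if (c <= 0) return List::create(Named("ok") = false);
    for (int k = 0; k < K; ++k) alpha[k] /= c;
    scale[0] = c;
    loglik += std::log(c) + bmax[0];
  }
  for (int t = 1; t < T; ++t) {
    double c = 0.0;
    for (int k = 0; k < K; ++k) {
      double s = 0.0;
      for (int j = 0; j < K; ++j) s += alpha[(size_t)(t - 1) * K + j] * trans(j, k);
      double v = s * b[(size_t)t * K + k];
      alpha[(size_t)t * K + k] = v;
      c += v;
    }
    if (c <= 0) return List::create(Named("ok") = false);
    for (int k = 0; k < K; ++k) alpha[(size_t)t * K + k] /= c;
    scale[t] = c;
    loglik += std::log(c) + bmax[t];
  }

  // backward sweep, accumulating sufficient statistics on the fly
  std::vector<double> beta(K, 1.0), beta_new(K);
  NumericMatrix xi_sum(K, K);            // expected transition counts
  NumericVector g_sum(K), gx_sum(K), gxx_sum(K), g0(K);
  {
    int t = T - 1;
    for (int k = 0; k < K; ++k) {
      double g = alpha[(size_t)t * K + k]; // beta = 1 at the last sample
      g_sum[k] += g;
      gx_sum[k] += g * x[t];
      gxx_sum[k] += g * x[t] * x[t];
    }
  }
  for (int t = T - 2; t >= 0; --t) {
    for (int j = 0; j < K; ++j) {
      double s = 0.0;
      for (int k = 0; k < K; ++k) {
        double term = trans(j, k) * b[(size_t)(t + 1) * K + k] * beta[k];
        s += term;
        xi_sum(j, k) += alpha[(size_t)t * K + j] * term / scale[t + 1];
      }
      beta_new[j] = s / scale[t + 1];
    }
    double gtot = 0.0;
    for (int j = 0; j < K; ++j) gtot += alpha[(size_t)t * K + j] * beta_new[j];
    for (int j = 0; j < K; ++j) {
      beta[j] = beta_new[j];
      double g = alpha[(size_t)t * K + j] * beta_new[j] / gtot;
      g_sum[j] += g;
      gx_sum[j] += g * x[t];
      gxx_sum[j] += g * x[t] * x[t];
      if (t == 0) g0[j] = g;
    }
  }
  if (T == 1) for (int k = 0; k < K; ++k) g0[k] = alpha[k];

  // M-step
  NumericVector new_init(K), new_means(K), new_sds(K);
  NumericMatrix new_trans(K, K);
  for (int k = 0; k < K; ++k) new_init[k] = g0[k];
  for (int j = 0; j < K; ++j) {
    double row = 0.0;
    for (int k = 0; k < K; ++k) row += xi_sum(j, k);
    for (int k = 0; k < K; ++k)
      new_trans(j, k) = row > 0 ? xi_sum(j, k) / row : (j == k ? 1.0 : 0.0);
  }
  for (int k = 0; k < K; ++k) {
    double g = g_sum[k];
    if (g <= 0) return List::create(Named("ok") = false);
    double m = gx_sum[k] / g;
    double v = gxx_sum[k] / g - m * m;
    new_means[k] = m;
    new_sds[k] = std::sqrt(v > 0 ? v : 0.0);
  }
  return List::create(
    Named("ok") = true, Named("loglik") = loglik, Named("init") = new_init,
    Named("trans") = new_trans, Named("means") = new_means,
    Named("sds") = new_sds, Named("gamma_sum") = g_sum);
}

// Viterbi decoding; ties broken toward the lower state index.
// [[Rcpp::export(name = ".tk_viterbi_cpp")]]
IntegerVector tk_viterbi_cpp(NumericVector x, NumericVector init,
                             NumericMatrix trans, NumericVector means,
                             NumericVector sds) {
  const int T = x.size(), K = means.size();
  std::vector<double> logtrans(K * K), delta(K), delta_new(K);
  for (int j = 0; j < K; ++j)
    for (int k = 0; k < K; ++k)
      logtrans[j * K + k] = trans(j, k) > 0 ? std::log(trans(j, k)) : -INFINITY;
  std::vector<int> back((size_t)T * K);
  for (int k = 0; k < K; ++k)
    delta[k] = (init[k] > 0 ? std::log(init[k]) : -INFINITY) +
               dnorm_log(x[0], means[k], sds[k]);
  for (int t = 1; t < T; ++t) {
    for (int k = 0; k < K; ++k) {
      double best = -INFINITY;
      int arg = 0;
      for (int j = 0; j < K; ++j) {
        double v = delta[j] + logtrans[j * K + k];
        if (v > best) { best = v; arg = j; }  // strict >: lower j wins ties
      }
      back[(size_t)t * K + k] = arg;
      delta_new[k] = best + dnorm_log(x[t], means[k], sds[k]);
    }
    std::swap(delta, delta_new);
  }
  IntegerVector path(T);
  int best = 0;
  for (int k = 1; k < K; ++k) if (delta[k] > delta[best]) best = k;
  path[T - 1] = best;
  for (int t = T - 1; t > 0; --t) {
    best = back[(size_t)t * K + best];
    path[t - 1] = best;
  }
  return path; // 0-based state indices
}
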