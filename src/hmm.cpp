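#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Scaled forward-backward pass for a Gaussian-emission HMM.
// Returns the log-likelihood plus the sufficient statistics needed for one
// Baum-Welch M-step: per-state expected counts, first and second moments of
// the observations under the posteriors, expected transition counts, and the
// time-1 posterior.  Hot loops run over raw buffers; emission densities are
// floored to keep degenerate states from zeroing whole columns.
// [[Rcpp::export]]
List hmm_estep(NumericVector x, NumericVector mu, NumericVector sigma,
               NumericMatrix A, NumericVector pi0, bool want_gamma = false) {
  const int n = x.size(), K = mu.size();
  const double tiny = 1e-300;
  const double *xp = x.begin();

  // emission densities, row-major [t*K + k]
  std::vector<double> B((size_t)n * K);
  for (int k = 0; k < K; ++k) {
    const double s = sigma[k], m = mu[k];
    const double c = -0.5 * std::log(2.0 * M_PI) - std::log(s);
    const double inv2s2 = 0.5 / (s * s);
    double *Bk = B.data() + k;
    for (int t = 0; t < n; ++t) {
      const double d = xp[t] - m;
      const double v = std::exp(c - d * d * inv2s2);
      Bk[(size_t)t * K] = v > tiny ? v : tiny;
    }
  }

  // transition matrix, row-major a[j*K + k] = A(j, k)
  std::vector<double> a((size_t)K * K);
  for (int j = 0; j < K; ++j)
    for (int k = 0; k < K; ++k) a[(size_t)j * K + k] = A(j, k);

  std::vector<double> alpha((size_t)n * K), beta((size_t)n * K), scale(n);
  double ll = 0.0;

  // forward
  {
    double tot = 0.0;
    for (int k = 0; k < K; ++k) {
      alpha[k] = pi0[k] * B[k];
      tot += alpha[k];
    }
    scale[0] = tot > tiny ? tot : tiny;
    const double inv = 1.0 / scale[0];
    for (int k = 0; k < K; ++k) alpha[k] *= inv;
  }
  for (int t = 1; t < n; ++t) {
    const double *ap = alpha.data() + (size_t)(t - 1) * K;
    const double *Bt = B.data() + (size_t)t * K;
    double *an = alpha.data() + (size_t)t * K;
    double tot = 0.0;
    for (int k = 0; k < K; ++k) {
      double s = 0.0;
      for (int j = 0; j < K; ++j) s += ap[j] * a[(size_t)j * K + k];
      an[k] = s * Bt[k];
      tot += an[k];
    }
    scale[t] = tot > tiny ? tot : tiny;
    const double inv = 1.0 / scale[t];
    for (int k = 0; k < K; ++k) an[k] *= inv;
  }
  for (int t = 0; t < n; ++t) ll += std::log(scale[t]);

  // backward
  for (int k = 0; k < K; ++k) beta[(size_t)(n - 1) * K + k] = 1.0;
  for (int t = n - 2; t >= 0; --t) {
    const double *bn = beta.data() + (size_t)(t + 1) * K;
    const double *Bt1 = B.data() + (size_t)(t + 1) * K;
    double *bt = beta.data() + (size_t)t * K;
    const double inv = 1.0 / scale[t + 1];
    for (int k = 0; k < K; ++k) {
      double s = 0.0;
      const double *ak = a.data() + (size_t)k * K;
      for (int j = 0; j < K; ++j) s += ak[j] * Bt1[j] * bn[j];
      bt[k] = s * inv;
    }
  }

  NumericVector g_sum(K), g_x(K), g_x2(K), gamma1(K);
  NumericMatrix xi(K, K);
  NumericMatrix gamma_out(want_gamma ? n : 1, K);
  std::vector<double> gs(K, 0.0), gx(K, 0.0), gx2(K, 0.0), g(K);
  std::vector<double> xis((size_t)K * K, 0.0);
  for (int t = 0; t < n; ++t) {
    const double *ap = alpha.data() + (size_t)t * K;
    const double *bp = beta.data() + (size_t)t * K;
    double norm = 0.0;
    for (int k = 0; k < K; ++k) {
      g[k] = ap[k] * bp[k];
      norm += g[k];
    }
    const double inv = 1.0 / (norm > 0 ? norm : tiny);
    const double xv = xp[t];
    for (int k = 0; k < K; ++k) {
      const double gk = g[k] * inv;
      gs[k] += gk;
      gx[k] += gk * xv;
      gx2[k] += gk * xv * xv;
      if (t == 0) gamma1[k] = gk;
      if (want_gamma) gamma_out(t, k) = gk;
    }
  }
  std::vector<double> tmp((size_t)K * K);
  for (int t = 0; t < n - 1; ++t) {
    const double *ap = alpha.data() + (size_t)t * K;
    const double *bn = beta.data() + (size_t)(t + 1) * K;
    const double *Bt1 = B.data() + (size_t)(t + 1) * K;
    double norm = 0.0;
    for (int j = 0; j < K; ++j) {
      const double aj = ap[j];
      const double *arow = a.data() + (size_t)j * K;
      double *trow = tmp.data() + (size_t)j * K;
      for (int k = 0; k < K; ++k) {
        const double v = aj * arow[k] * Bt1[k] * bn[k];
        trow[k] = v;
        norm += v;
      }
    }
    const double inv = 1.0 / (norm > 0 ? norm : tiny);
    for (int jk = 0; jk < K * K; ++jk) xis[jk] += tmp[jk] * inv;
  }
  for (int k = 0; k < K; ++k) {
    g_sum[k] = gs[k];
    g_x[k] = gx[k];
    g_x2[k] = gx2[k];
  }
  for (int j = 0; j < K; ++j)
    for (int k = 0; k < K; ++k) xi(j, k) = xis[(size_t)j * K + k];

  List out = List::create(_["loglik"] = ll, _["gamma_sum"] = g_sum,
                          _["gamma_x"] = g_x, _["gamma_x2"] = g_x2,
                          _["xi_sum"] = xi, _["gamma1"] = gamma1);
  if (want_gamma) out["gamma"] = gamma_out;
  return out;
}

// Viterbi decoding in log space; ties broken toward the lower state index.
// [[Rcpp::export]]
IntegerVector hmm_viterbi(NumericVector x, NumericVector mu, NumericVector sigma,
                          NumericMatrix A, NumericVector pi0) {
  const int n = x.size(), K = mu.size();
  const double neginf = -1e308;
  const double *xp = x.begin();
  std::vector<double> c(K), inv2s2(K), logA((size_t)K * K);
  for (int k = 0; k < K; ++k) {
    c[k] = -0.5 * std::log(2.0 * M_PI) - std::log(sigma[k]);
    inv2s2[k] = 0.5 / (sigma[k] * sigma[k]);
  }
  for (int j = 0; j < K; ++j)
    for (int k = 0; k < K; ++k)
      logA[(size_t)j * K + k] = A(j, k) > 0 ? std::log(A(j, k)) : neginf;

  std::vector<double> prev(K), cur(K);
  std::vector<int> psi((size_t)n * K);
  for (int k = 0; k < K; ++k) {
    const double d = xp[0] - mu[k];
    prev[k] = (pi0[k] > 0 ? std::log(pi0[k]) : neginf) + c[k] -
      d * d * inv2s2[k];
  }
  for (int t = 1; t < n; ++t) {
    int *psit = psi.data() + (size_t)t * K;
    for (int k = 0; k < K; ++k) {
      int arg = 0;
      double best = prev[0] + logA[k];
      for (int j = 1; j < K; ++j) {
        const double v = prev[j] + logA[(size_t)j * K + k];
        if (v > best) { best = v; arg = j; }   // strict >: ties keep lower j
      }
      const double d = xp[t] - mu[k];
      cur[k] = best + c[k] - d * d * inv2s2[k];
      psit[k] = arg;
    }
    std::swap(prev, cur);
  }
  IntegerVector path(n);
  int arg = 0;
  double best = prev[0];
  for (int k = 1; k < K; ++k)
    if (prev[k] > best) { best = prev[k]; arg = k; }
  path[n - 1] = arg;
  for (int t = n - 2; t >= 0; --t)
    path[t] = psi[(size_t)(t + 1) * K + path[t + 1]];
  for (int t = 0; t < n; ++t) path[t] += 1;  // 1-based states for R
  return path;
}
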