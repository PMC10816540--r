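#include <Rcpp.h>
using namespace Rcpp;

// EM for a one-dimensional K-component Gaussian mixture.
// Returns ok = false when a component collapses (empty responsibility) or
// the likelihood degenerates; the caller treats that restart as failed.
// [[Rcpp::export]]
List em_gmm1d_cpp(NumericVector x, NumericVector mu0, NumericVector w0,
                  NumericVector sd0, double tol, int max_iter,
                  double floor_sd) {
  const int n = x.size();
  const int K = mu0.size();
  std::vector<double> mu(mu0.begin(), mu0.end());
  std::vector<double> w(w0.begin(), w0.end());
  std::vector<double> sd(sd0.begin(), sd0.end());
  std::vector<double> post(static_cast<size_t>(n) * K);
  std::vector<double> ld(K), logw(K), logsd(K), nk(K);
  std::vector<double> trace;
  trace.reserve(max_iter > 1024 ? 1024 : max_iter);
  const double HL2PI = 0.5 * std::log(2.0 * M_PI);
  double prev = R_NegInf, prev2 = R_NegInf, logL = R_NegInf;
  bool converged = false;

  for (int it = 0; it < max_iter; ++it) {
    for (int k = 0; k < K; ++k) {
      logw[k] = std::log(w[k]);
      logsd[k] = std::log(sd[k]);
    }
    // E-step. Weighted densities are computed directly (one exp per
    // observation-component); the rare all-underflow rows fall back to a
    // stabilized log-sum-exp.
    double ll = 0.0;
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int k = 0; k < K; ++k) {
        const double z = (x[i] - mu[k]) / sd[k];
        ld[k] = std::exp(-0.5 * z * z + logw[k] - logsd[k] - HL2PI);
        s += ld[k];
      }
      if (s > 0.0) {
        ll += std::log(s);
        for (int k = 0; k < K; ++k)
          post[i + static_cast<size_t>(n) * k] = ld[k] / s;
      } else {
        double m = R_NegInf;
        for (int k = 0; k < K; ++k) {
          const double z = (x[i] - mu[k]) / sd[k];
          ld[k] = -0.5 * z * z + logw[k] - logsd[k] - HL2PI;
          if (ld[k] > m) m = ld[k];
        }
        double se = 0.0;
        for (int k = 0; k < K; ++k) se += std::exp(ld[k] - m);
        const double lse = m + std::log(se);
        ll += lse;
        for (int k = 0; k < K; ++k)
          post[i + static_cast<size_t>(n) * k] = std::exp(ld[k] - lse);
      }
    }
    if (!std::isfinite(ll)) return List::create(Named("ok") = false);
    logL = ll;
    trace.push_back(ll);
    // Aitken-accelerated convergence: EM converges linearly, so project the
    // asymptotic log-likelihood and stop once it is within tol (falls back
    // to the raw difference when the acceleration ratio is unusable).
    if (it > 0) {
      const double d1 = ll - prev;
      if (d1 < tol) {
        converged = true;
        break;
      }
      if (it > 1) {
        const double d0 = prev - prev2;
        if (d0 > 0.0) {
          const double a = d1 / d0;
          if (a > 0.0 && a < 1.0) {
            const double l_inf = prev + d1 / (1.0 - a);
            if (l_inf - ll < tol) {
              converged = true;
              break;
            }
          }
        }
      }
    }
    prev2 = prev;
    prev = ll;
    // M-step
    for (int k = 0; k < K; ++k) {
      const double *pk = &post[static_cast<size_t>(n) * k];
      double s = 0.0, sx = 0.0;
      for (int i = 0; i < n; ++i) {
        s += pk[i];
        sx += pk[i] * x[i];
      }
      if (s < 1e-10) return List::create(Named("ok") = false);
      nk[k] = s;
      w[k] = s / n;
      mu[k] = sx / s;
      double sv = 0.0;
      for (int i = 0; i < n; ++i) {
        const double d = x[i] - mu[k];
        sv += pk[i] * d * d;
      }
      sd[k] = std::sqrt(sv / s);
      if (sd[k] < floor_sd) sd[k] = floor_sd;
    }
  }
  return List::create(
    Named("ok") = true,
    Named("weights") = NumericVector(w.begin(), w.end()),
    Named("means") = NumericVector(mu.begin(), mu.end()),
    Named("sds") = NumericVector(sd.begin(), sd.end()),
    Named("logL") = logL,
    Named("converged") = converged,
    Named("logL_trace") = NumericVector(trace.begin(), trace.end()));
}
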