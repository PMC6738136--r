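#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// EM for a univariate Gaussian mixture with an optional Uniform(0,1)
// component. Means and/or weights may be held fixed; standard deviations are
// always re-estimated (floored and capped). Returns the fitted parameters,
// the log-likelihood trace (non-decreasing) and final responsibilities.
// [[Rcpp::export(name = ".em_gauss_cpp")]]
List em_gauss_cpp(NumericVector y, NumericVector means0, NumericVector sds0,
                  NumericVector weights0, bool fix_means, bool fix_weights,
                  bool uniform, double uniform_w, int max_iter, double tol,
                  double sd_floor, double sd_cap) {
  const int n = y.size();
  const int K = means0.size();
  std::vector<double> mu(means0.begin(), means0.end());
  std::vector<double> sd(sds0.begin(), sds0.end());
  std::vector<double> w(weights0.begin(), weights0.end());
  double uw = uniform ? uniform_w : 0.0;
  {
    double sw = 0.0;
    for (int k = 0; k < K; ++k) sw += w[k];
    for (int k = 0; k < K; ++k) w[k] *= (1.0 - uw) / sw;
  }
  const double SQRT2PI = 2.5066282746310002;
  NumericMatrix resp(n, K + (uniform ? 1 : 0));
  std::vector<double> ll_trace;
  ll_trace.reserve(max_iter);
  double ll_old = R_NegInf;
  std::vector<double> nk(K + 1), sum_ry(K), sum_rd(K);
  for (int it = 0; it < max_iter; ++it) {
    double ll = 0.0;
    std::fill(nk.begin(), nk.end(), 0.0);
    std::fill(sum_ry.begin(), sum_ry.end(), 0.0);
    std::fill(sum_rd.begin(), sum_rd.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      double tot = 0.0;
      for (int k = 0; k < K; ++k) {
        double z = (y[i] - mu[k]) / sd[k];
        double d = w[k] * std::exp(-0.5 * z * z) / (sd[k] * SQRT2PI);
        resp(i, k) = d;
        tot += d;
      }
      if (uniform) {
        resp(i, K) = uw;
        tot += uw;
      }
      if (tot < 1e-300) tot = 1e-300;
      ll += std::log(tot);
      for (int k = 0; k < K + (uniform ? 1 : 0); ++k) {
        double r = resp(i, k) / tot;
        resp(i, k) = r;
        nk[k] += r;
        if (k < K) {
          sum_ry[k] += r * y[i];
          double dev = y[i] - mu[k];
          sum_rd[k] += r * dev * dev;
        }
      }
    }
    ll_trace.push_back(ll);
    if (R_finite(ll_old) && ll - ll_old < tol) break;
    ll_old = ll;
    if (!fix_means)
      for (int k = 0; k < K; ++k)
        if (nk[k] > 0) mu[k] = sum_ry[k] / nk[k];
    for (int k = 0; k < K; ++k) {
      if (nk[k] <= 0) continue;
      // recompute spread around the (possibly updated) mean
      double v;
      if (!fix_means) {
        // responsibilities were computed before the mean moved; adjust
        double mean_shift = 0.0; // exact recomputation below
        (void)mean_shift;
        double s2 = 0.0;
        for (int i = 0; i < n; ++i) {
          double dev = y[i] - mu[k];
          s2 += resp(i, k) * dev * dev;
        }
        v = s2 / nk[k];
      } else {
        v = sum_rd[k] / nk[k];
      }
      double s = std::sqrt(v);
      if (s < sd_floor) s = sd_floor;
      if (s > sd_cap) s = sd_cap;
      sd[k] = s;
    }
    if (!fix_weights) {
      if (uniform) {
        uw = nk[K] / n;
        for (int k = 0; k < K; ++k) w[k] = nk[k] / n;
      } else {
        for (int k = 0; k < K; ++k) w[k] = nk[k] / n;
      }
    }
  }
  // final responsibilities under the final parameters
  for (int i = 0; i < n; ++i) {
    double tot = 0.0;
    for (int k = 0; k < K; ++k) {
      double z = (y[i] - mu[k]) / sd[k];
      double d = w[k] * std::exp(-0.5 * z * z) / (sd[k] * SQRT2PI);
      resp(i, k) = d;
      tot += d;
    }
    if (uniform) {
      resp(i, K) = uw;
      tot += uw;
    }
    if (tot < 1e-300) tot = 1e-300;
    for (int k = 0; k < K + (uniform ? 1 : 0); ++k) resp(i, k) /= tot;
  }
  return List::create(
      Named("means") = NumericVector(mu.begin(), mu.end()),
      Named("sds") = NumericVector(sd.begin(), sd.end()),
      Named("weights") = NumericVector(w.begin(), w.end()),
      Named("uniform_w") = uw,
      Named("ll_trace") = NumericVector(ll_trace.begin(), ll_trace.end()),
      Named("responsibilities") = resp);
}
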