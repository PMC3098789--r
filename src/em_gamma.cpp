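// EM engine for per-probeset two-component gamma mixtures.
//
// Each row of X is fitted independently from the supplied start; the R
// wrapper owns initialization (median and two-means splits), start
// selection by log-likelihood, component relabeling and scale mapping.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;


// weighted gamma MLE: Newton on log(k) - digamma(k) = s
static double gamma_shape_mle(double s, double k_init) {
  if (!std::isfinite(s) || s <= 0.0) s = 1e-8;
  double k = (3.0 - s + std::sqrt((s - 3.0) * (s - 3.0) + 24.0 * s)) /
             (12.0 * s);
  if (std::isfinite(k_init) && k_init > 1e-3 && k_init < 1e6) k = k_init;
  for (int it = 0; it < 25; ++it) {
    double step = (std::log(k) - R::digamma(k) - s) /
                  (1.0 / k - R::trigamma(k));
    double k_new = k - step;
    if (!std::isfinite(k_new) || k_new <= 0.0) k_new = k / 2.0;
    double moved = std::fabs(k_new - k) / k;
    k = k_new;
    if (moved < 1e-9) break;
  }
  if (k < 1e-3) k = 1e-3;
  if (k > 1e6) k = 1e6;
  return k;
}

// [[Rcpp::export(name = ".em_gamma_rows_cpp")]]
List em_gamma_rows(NumericMatrix X, NumericVector w0,
                   NumericVector k1_0, NumericVector t1_0,
                   NumericVector k2_0, NumericVector t2_0,
                   int max_iter, double tol, bool want_trace) {
  const int nr = X.nrow(), nc = X.ncol();
  NumericVector w(nr), k1(nr), t1(nr), k2(nr), t2(nr), ll_out(nr);
  LogicalVector converged(nr), collapsed(nr);
  IntegerVector n_iter(nr);
  std::vector<double> trace;  // first row only, when requested

  std::vector<double> lx(nc), r(nc);
  for (int i = 0; i < nr; ++i) {
    double wi = w0[i], k1i = k1_0[i], t1i = t1_0[i],
           k2i = k2_0[i], t2i = t2_0[i];
    for (int j = 0; j < nc; ++j) lx[j] = std::log(X(i, j));
    double ll_old = R_NegInf, ll = NA_REAL;
    bool conv = false, coll = false;
    int iter = 0;
    while (iter < max_iter) {
      ++iter;
      // E-step likelihoods and row log-likelihood; per-component
      // normalizing constants are hoisted out of the sample loop
      double c1 = std::log(wi) - k1i * std::log(t1i) - std::lgamma(k1i);
      double c2 = std::log1p(-wi) - k2i * std::log(t2i) - std::lgamma(k2i);
      double ll_new = 0.0;
      for (int j = 0; j < nc; ++j) {
        double a1 = c1 + (k1i - 1.0) * lx[j] - X(i, j) / t1i;
        double a2 = c2 + (k2i - 1.0) * lx[j] - X(i, j) / t2i;
        double m = a1 > a2 ? a1 : a2;
        if (!std::isfinite(m)) { ll_new = -DBL_MAX; break; }
        ll_new += m + std::log(std::exp(a1 - m) + std::exp(a2 - m));
        r[j] = 1.0 / (1.0 + std::exp(a2 - a1));
      }
      if (!std::isfinite(ll_new)) ll_new = -DBL_MAX;
      ll = ll_new;
      if (want_trace && i == 0) trace.push_back(ll);
      if (std::isfinite(ll_old) &&
          std::fabs(ll - ll_old) < tol * (std::fabs(ll_old) + tol)) {
        conv = true;
        break;
      }
      ll_old = ll;
      // M-step
      double sw = 0.0;
      for (int j = 0; j < nc; ++j) sw += r[j];
      double w_new = sw / nc;
      if (w_new < 1e-3 || w_new > 1.0 - 1e-3) { coll = true; break; }
      wi = w_new;
      for (int comp = 0; comp < 2; ++comp) {
        double srw = 0.0, sx = 0.0, slx = 0.0;
        for (int j = 0; j < nc; ++j) {
          double rc = comp == 0 ? r[j] : 1.0 - r[j];
          srw += rc; sx += rc * X(i, j); slx += rc * lx[j];
        }
        if (srw <= 0.0) { coll = true; break; }
        double mx = sx / srw, mlx = slx / srw;
        double k = gamma_shape_mle(std::log(mx) - mlx,
                                   comp == 0 ? k1i : k2i);
        if (comp == 0) { k1i = k; t1i = mx / k; }
        else { k2i = k; t2i = mx / k; }
      }
      if (coll) break;
    }
    w[i] = wi; k1[i] = k1i; t1[i] = t1i; k2[i] = k2i; t2[i] = t2i;
    ll_out[i] = ll;
    converged[i] = conv;
    collapsed[i] = coll;
    n_iter[i] = iter;
  }
  return List::create(_["w"] = w, _["k1"] = k1, _["t1"] = t1,
                      _["k2"] = k2, _["t2"] = t2, _["loglik"] = ll_out,
                      _["converged"] = converged,
                      _["collapsed"] = collapsed, _["n_iter"] = n_iter,
                      _["trace"] = wrap(trace));
}
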