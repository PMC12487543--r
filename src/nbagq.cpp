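// Marginal likelihood of a negative binomial (NB2) regression with a
// Gaussian city random intercept, integrated by mode-centered adaptive
// Gauss-Hermite quadrature. Returns the log-likelihood and, on request,
// the analytic gradient, per-city score vectors and the Hessian with the
// quadrature points frozen at the current adaptive centering (the
// adaptation terms cancel to the order of the quadrature error because the
// centering is a stationary point of the integrand).
//
// Parameter vector: theta = (beta[0..p-1], log(alpha), log(sigma)).
// NB2: Var = mu + alpha * mu^2; a = 1/alpha.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
List nbagq_core(NumericVector y, NumericMatrix X, NumericVector off,
                IntegerVector city_start, IntegerVector city_len,
                NumericVector beta, double log_alpha, double log_sigma,
                NumericVector gh_z, NumericVector gh_w,
                NumericVector b_init,
                bool want_grad, bool want_scores, bool want_hess,
                bool sigma_zero) {
  const int n = y.size();
  const int p = X.ncol();
  const int G = city_start.size();
  const int K = gh_z.size();
  const int q = p + 2;

  const double alpha = std::exp(log_alpha);
  const double a = 1.0 / alpha;
  const double log_a = std::log(a);
  const double lgam_a = R::lgammafn(a);
  const double dig_a = R::digamma(a);
  const double trig_a = R::trigamma(a);
  const double sigma = sigma_zero ? 0.0 : std::exp(log_sigma);
  const double sig2 = sigma * sigma;

  // linear predictor and y-dependent constants
  std::vector<double> eta(n), cc(n), dig_ya(n), trig_ya(n);
  for (int i = 0; i < n; ++i) {
    double e = off[i];
    for (int j = 0; j < p; ++j) e += X(i, j) * beta[j];
    eta[i] = e;
    cc[i] = R::lgammafn(y[i] + a) - lgam_a - R::lgammafn(y[i] + 1.0) +
            a * log_a;
    if (want_grad || want_scores || want_hess) {
      dig_ya[i] = R::digamma(y[i] + a);
      if (want_hess) trig_ya[i] = R::trigamma(y[i] + a);
    }
  }

  double loglik = 0.0;
  NumericVector grad(q);
  NumericMatrix scores(want_scores ? G : 1, want_scores ? q : 1);
  NumericMatrix H(want_hess ? q : 1, want_hess ? q : 1);
  NumericVector b_hat(G);

  std::vector<double> tk(K), om(K);
  std::vector<double> vtil, utiltk; // per-stratum omega-weighted v and du/dt

  bool any_deriv = want_grad || want_scores || want_hess;

  for (int c = 0; c < G; ++c) {
    const int s0 = city_start[c];
    const int nc = city_len[c];

    if (sigma_zero) {
      // degenerate random effect: plain NB2 log-likelihood at b = 0
      double Lc = 0.0;
      std::vector<double> dloc(q, 0.0);
      for (int ii = 0; ii < nc; ++ii) {
        int i = s0 + ii;
        double mu = std::exp(eta[i]);
        Lc += cc[i] + y[i] * eta[i] - (y[i] + a) * std::log(a + mu);
        if (any_deriv) {
          double u = y[i] - (y[i] + a) * mu / (a + mu);
          for (int j = 0; j < p; ++j) dloc[j] += X(i, j) * u;
          double fa = dig_ya[i] - dig_a + log_a + 1.0 -
                      std::log(a + mu) - (y[i] + a) / (a + mu);
          dloc[p] += -a * fa;
          if (want_hess) {
            double v = -(y[i] + a) * a * mu / ((a + mu) * (a + mu));
            for (int j = 0; j < p; ++j)
              for (int l = j; l < p; ++l)
                H(j, l) += X(i, j) * X(i, l) * v;
            double dudt = a * mu / (a + mu) -
                          a * (y[i] + a) * mu / ((a + mu) * (a + mu));
            for (int j = 0; j < p; ++j) H(j, p) += X(i, j) * dudt;
            double faa = trig_ya[i] - trig_a + 1.0 / a - 2.0 / (a + mu) +
                         (y[i] + a) / ((a + mu) * (a + mu));
            H(p, p) += a * fa + a * a * faa;
          }
        }
      }
      loglik += Lc;
      b_hat[c] = 0.0;
      if (any_deriv) {
        for (int j = 0; j < q; ++j) {
          grad[j] += dloc[j];
          if (want_scores) scores(c, j) = dloc[j];
        }
      }
      continue;
    }

    // Newton search for the mode of h(b) = sum_i f_i(b) + log phi(b; 0, sig2)
    double b = b_init.size() == G ? b_init[c] : 0.0;
    double h1 = 0.0, h2 = 0.0;
    for (int it = 0; it < 200; ++it) {
      h1 = -b / sig2;
      h2 = -1.0 / sig2;
      for (int ii = 0; ii < nc; ++ii) {
        int i = s0 + ii;
        double mu = std::exp(eta[i] + b);
        h1 += y[i] - (y[i] + a) * mu / (a + mu);
        h2 += -(y[i] + a) * a * mu / ((a + mu) * (a + mu));
      }
      double step = h1 / h2;
      if (step > 5.0) step = 5.0;
      if (step < -5.0) step = -5.0;
      b -= step;
      if (std::fabs(step) < 1e-11) break;
    }
    b_hat[c] = b;
    // curvature at the mode
    h2 = -1.0 / sig2;
    for (int ii = 0; ii < nc; ++ii) {
      int i = s0 + ii;
      double mu = std::exp(eta[i] + b);
      h2 += -(y[i] + a) * a * mu / ((a + mu) * (a + mu));
    }
    double shat = 1.0 / std::sqrt(-h2);

    // node values of h(b_k) + z_k^2 + log w_k
    double tmax = -INFINITY;
    for (int k = 0; k < K; ++k) {
      double bk = b + M_SQRT2 * shat * gh_z[k];
      double hk = -0.5 * std::log(2.0 * M_PI) - std::log(sigma) -
                  bk * bk / (2.0 * sig2);
      for (int ii = 0; ii < nc; ++ii) {
        int i = s0 + ii;
        double mu = std::exp(eta[i] + bk);
        hk += cc[i] + y[i] * (eta[i] + bk) - (y[i] + a) * std::log(a + mu);
      }
      tk[k] = hk + gh_z[k] * gh_z[k] + std::log(gh_w[k]);
      if (tk[k] > tmax) tmax = tk[k];
    }
    double ssum = 0.0;
    for (int k = 0; k < K; ++k) { om[k] = std::exp(tk[k] - tmax); ssum += om[k]; }
    loglik += std::log(M_SQRT2 * shat) + tmax + std::log(ssum);
    if (!any_deriv) continue;
    for (int k = 0; k < K; ++k) om[k] /= ssum;

    // omega-weighted derivative accumulation (quadrature points frozen)
    std::vector<double> dloc(q, 0.0);       // city score
    std::vector<double> dk(q);              // per-node derivative
    NumericMatrix Hdd(want_hess ? q : 1, want_hess ? q : 1);
    double s_tt = 0.0, s_lsls = 0.0;
    vtil.assign(nc, 0.0);
    utiltk.assign(nc, 0.0);
    for (int k = 0; k < K; ++k) {
      double bk = b + M_SQRT2 * shat * gh_z[k];
      std::fill(dk.begin(), dk.end(), 0.0);
      double sum_fa = 0.0;
      for (int ii = 0; ii < nc; ++ii) {
        int i = s0 + ii;
        double mu = std::exp(eta[i] + bk);
        double apm = a + mu;
        double u = y[i] - (y[i] + a) * mu / apm;
        for (int j = 0; j < p; ++j) dk[j] += X(i, j) * u;
        double fa = dig_ya[i] - dig_a + log_a + 1.0 - std::log(apm) -
                    (y[i] + a) / apm;
        sum_fa += fa;
        if (want_hess) {
          vtil[ii] += om[k] * (-(y[i] + a) * a * mu / (apm * apm));
          utiltk[ii] += om[k] *
            (a * mu / apm - a * (y[i] + a) * mu / (apm * apm));
          double faa = trig_ya[i] - trig_a + 1.0 / a - 2.0 / apm +
                       (y[i] + a) / (apm * apm);
          s_tt += om[k] * (a * fa + a * a * faa);
        }
      }
      dk[p] = -a * sum_fa;
      dk[p + 1] = bk * bk / sig2 - 1.0;
      if (want_hess) s_lsls += om[k] * (-2.0 * bk * bk / sig2);
      for (int j = 0; j < q; ++j) dloc[j] += om[k] * dk[j];
      if (want_hess) {
        for (int j = 0; j < q; ++j)
          for (int l = j; l < q; ++l)
            Hdd(j, l) += om[k] * dk[j] * dk[l];
      }
    }
    for (int j = 0; j < q; ++j) {
      grad[j] += dloc[j];
      if (want_scores) scores(c, j) = dloc[j];
    }
    if (want_hess) {
      // E[D] blocks
      for (int ii = 0; ii < nc; ++ii) {
        int i = s0 + ii;
        for (int j = 0; j < p; ++j) {
          for (int l = j; l < p; ++l) H(j, l) += X(i, j) * X(i, l) * vtil[ii];
          H(j, p) += X(i, j) * utiltk[ii];
        }
      }
      H(p, p) += s_tt;
      H(p + 1, p + 1) += s_lsls;
      // + E[d d'] - E[d] E[d]'
      for (int j = 0; j < q; ++j)
        for (int l = j; l < q; ++l)
          H(j, l) += Hdd(j, l) - dloc[j] * dloc[l];
    }
  }

  if (want_hess) {
    for (int j = 0; j < q; ++j)
      for (int l = 0; l < j; ++l)
        H(j, l) = H(l, j);
  }

  List out = List::create(_["loglik"] = loglik, _["b_hat"] = b_hat);
  if (want_grad || want_scores || want_hess) out["grad"] = grad;
  if (want_scores) out["scores"] = scores;
  if (want_hess) out["hessian"] = H;
  return out;
}
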