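#include <Rcpp.h>
using namespace Rcpp;

// Concentration for a transit-absorption model with one- or two-compartment
// disposition and multiple bolus doses.
//
// The transit chain delivers drug into the depot at rate
//   r(t) = dose * ktr * (ktr t)^N * exp(-ktr t) / Gamma(N + 1),
// ktr = (N + 1) / MTT, i.e. a gamma(N + 1, ktr) density scaled by dose
// (log-gamma arithmetic, so N is a nonnegative real). The unit impulse
// response of depot -ka-> central with linear mammillary disposition is a
// sum of exponential modes c_m exp(-lambda_m t); the concentration is the
// convolution of the two. Each mode convolves in closed form through the
// regularised incomplete gamma function when ktr > lambda_m,
//   I(t) = exp(-lambda t) (ktr/(ktr-lambda))^(N+1) P(N+1, (ktr-lambda) t),
// evaluated in log space; modes with lambda close to or above ktr fall back
// to two-panel Gauss-Legendre quadrature (one panel over the gamma mass,
// one over the remainder of [0, t]).
//
// Set q = 0 for one-compartment disposition (the beta mode vanishes).

static double conv_mode(double tt, double lambda, double shape, double ktr,
                        double tq, const NumericVector &glx,
                        const NumericVector &glw) {
  double d = ktr - lambda;
  if (d > 1e-3 * ktr) {
    double logP = R::pgamma(d * tt, shape, 1.0, 1, 1);
    return std::exp(-lambda * tt + shape * (std::log(ktr) - std::log(d)) + logP);
  }
  // quadrature fallback: integrand g(s) exp(-lambda (t - s))
  const int nq = glx.size();
  double lggam = std::lgamma(shape);
  double acc = 0.0;
  double b1 = (tt < tq) ? tt : tq;  // panel 1: [0, b1]
  for (int k = 0; k < nq; ++k) {
    double s = 0.5 * b1 * (glx[k] + 1.0);
    double w = 0.5 * b1 * glw[k];
    if (s <= 0.0) continue;
    double lg = shape * std::log(ktr) + (shape - 1.0) * std::log(s) -
                ktr * s - lggam;
    acc += w * std::exp(lg - lambda * (tt - s));
  }
  if (tt > tq) {  // panel 2: [tq, t]
    for (int k = 0; k < nq; ++k) {
      double s = tq + 0.5 * (tt - tq) * (glx[k] + 1.0);
      double w = 0.5 * (tt - tq) * glw[k];
      double lg = shape * std::log(ktr) + (shape - 1.0) * std::log(s) -
                  ktr * s - lggam;
      acc += w * std::exp(lg - lambda * (tt - s));
    }
  }
  return acc;
}

// [[Rcpp::export]]
NumericVector conc_transit_cpp(NumericVector times,
                               NumericVector dose_t, NumericVector dose_amt,
                               double cl, double v1, double q, double v2,
                               double ka, double mtt, double n,
                               NumericVector glx, NumericVector glw) {
  const int nt = times.size(), nd = dose_t.size();
  NumericVector out(nt);

  double k10 = cl / v1;
  double k12 = (v2 > 0.0) ? q / v1 : 0.0;
  double k21 = (v2 > 0.0) ? q / v2 : 0.0;
  double s2 = k10 + k12 + k21;
  double disc2 = s2 * s2 - 4.0 * k10 * k21;
  if (disc2 < 1e-14 * s2 * s2) {  // nudge away from a repeated root
    k21 *= 1.0 + 1e-7;
    s2 = k10 + k12 + k21;
    disc2 = s2 * s2 - 4.0 * k10 * k21;
  }
  double disc = std::sqrt(std::max(disc2, 0.0));
  double alpha = 0.5 * (s2 + disc), beta = 0.5 * (s2 - disc);

  if (std::fabs(ka - alpha) < 1e-9 * (ka + alpha)) ka *= 1.0 + 1e-8;
  if (std::fabs(ka - beta) < 1e-9 * (ka + beta)) ka *= 1.0 + 1e-8;

  // unit-bolus-central amount A_c(t) = ralpha e^{-alpha t} + rbeta e^{-beta t}
  double ralpha = (alpha > beta) ? (alpha - k21) / (alpha - beta) : 1.0;
  double rbeta = 1.0 - ralpha;
  // unit-depot-dose response: three modes
  double lam[3], cc[3];
  lam[0] = alpha; cc[0] = ralpha * ka / (ka - alpha);
  lam[1] = beta;  cc[1] = (rbeta != 0.0) ? rbeta * ka / (ka - beta) : 0.0;
  lam[2] = ka;    cc[2] = -(cc[0] + cc[1]);

  double shape = n + 1.0;
  double ktr = shape / mtt;
  double tq = R::qgamma(1.0 - 1e-9, shape, 1.0 / ktr, 1, 0);

  for (int d = 0; d < nd; ++d) {
    double td = dose_t[d], amt = dose_amt[d];
    if (amt == 0.0) continue;
    for (int i = 0; i < nt; ++i) {
      double tt = times[i] - td;
      if (tt <= 0.0) continue;
      double acc = 0.0;
      for (int m = 0; m < 3; ++m) {
        if (cc[m] == 0.0) continue;
        acc += cc[m] * conv_mode(tt, lam[m], shape, ktr, tq, glx, glw);
      }
      out[i] += amt * acc;
    }
  }
  for (int i = 0; i < nt; ++i) {
    out[i] /= v1;
    if (out[i] < 0.0) out[i] = 0.0;  // round-off guard
  }
  return out;
}
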