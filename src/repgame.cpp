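#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Residuals of the log-moment matching system:
//   digamma(mu+1) - digamma(mu+lam+2) = lx
//   digamma(lam+1) - digamma(mu+lam+2) = l1x
static inline void lm_resid(double mu, double la, double lx, double l1x,
                            double &f1, double &f2) {
  double d = R::digamma(mu + la + 2.0);
  f1 = R::digamma(mu + 1.0) - d - lx;
  f2 = R::digamma(la + 1.0) - d - l1x;
}

// Solve for the beta exponents whose log-moments <ln x>, <ln(1-x)> equal
// (lx, l1x), by damped Newton iteration on the digamma system.  Both
// exponents are constrained to (-1, Inf).  Non-convergence is an error,
// never silently ignored.
// [[Rcpp::export]]
NumericVector kl_compress_newton(double lx, double l1x,
                                 double mu0, double la0,
                                 double tol = 1e-10, int maxit = 200) {
  const double lo = -1.0 + 1e-12;
  double mu = (mu0 > lo) ? mu0 : lo + 1e-9;
  double la = (la0 > lo) ? la0 : lo + 1e-9;
  double f1, f2;
  lm_resid(mu, la, lx, l1x, f1, f2);
  double err = std::max(std::fabs(f1), std::fabs(f2));
  int it = 0;
  while (err > tol) {
    if (++it > maxit)
      stop("KL-optimal compression did not converge in %d iterations", maxit);
    double t = R::trigamma(mu + la + 2.0);
    double a = R::trigamma(mu + 1.0) - t;   // dF1/dmu
    double b = -t;                           // dF1/dla = dF2/dmu
    double c = R::trigamma(la + 1.0) - t;   // dF2/dla
    double det = a * c - b * b;
    if (det == 0.0 || !std::isfinite(det))
      stop("singular Jacobian in KL-optimal compression");
    double dmu = -(c * f1 - b * f2) / det;
    double dla = -(-b * f1 + a * f2) / det;
    // step halving until the residual decreases and the domain is respected
    double step = 1.0;
    bool ok = false;
    double nmu = mu, nla = la, g1 = f1, g2 = f2, nerr = err;
    for (int h = 0; h < 60; ++h) {
      nmu = mu + step * dmu;
      nla = la + step * dla;
      if (nmu > lo && nla > lo) {
        lm_resid(nmu, nla, lx, l1x, g1, g2);
        nerr = std::max(std::fabs(g1), std::fabs(g2));
        if (std::isfinite(nerr) && nerr < err) { ok = true; break; }
      }
      step *= 0.5;
    }
    if (!ok)
      stop("line search failed in KL-optimal compression (lx=%f l1x=%f mu0=%f la0=%f mu=%f la=%f)", lx, l1x, mu0, la0, mu, la);
    mu = nmu; la = nla; f1 = g1; f2 = g2; err = nerr;
  }
  return NumericVector::create(mu, la);
}

// KL divergence D(Beta(mu+d, lam) || Beta(mu, lam)) as a function of the
// positive shift d of the first exponent (closed form).
static inline double kl_shift(double mu, double la, double d) {
  return R::lbeta(mu + 1.0, la + 1.0) - R::lbeta(mu + d + 1.0, la + 1.0) +
         d * (R::digamma(mu + d + 1.0) - R::digamma(mu + d + la + 2.0));
}

// Size a lie: the unique positive shift d of the mu exponent such that the
// shifted belief diverges from the base by `target` nats.  Shifts of the
// lambda exponent are obtained by calling with mu and lambda swapped
// (mirror symmetry x -> 1-x).  Monotone in d, solved by bisection.  When
// the other exponent is near -1 the divergence grows only logarithmically
// in d and the target may be unreachable; the shift is then capped.
// [[Rcpp::export]]
double lie_delta(double mu, double la, double target,
                 double tol = 1e-9, int maxit = 400, double cap = 1e3) {
  if (target <= 0.0) return 0.0;
  if (kl_shift(mu, la, cap) < target) return cap;
  double hi = 1.0;
  int it = 0;
  while (kl_shift(mu, la, hi) < target) {
    hi *= 2.0;
    if (++it > 200)
      stop("lie size solver failed to bracket the target divergence");
  }
  double lo = 0.0;
  for (it = 0; it < maxit; ++it) {
    double mid = 0.5 * (lo + hi);
    if (kl_shift(mu, la, mid) < target) lo = mid; else hi = mid;
    if (hi - lo < tol * (1.0 + hi)) break;
  }
  return 0.5 * (lo + hi);
}
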