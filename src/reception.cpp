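// In-place hot path of the simulation engine: the full receiver pipeline
// and the speaker-side theory-of-mind bookkeeping, mirroring exactly the
// R-level operations (assess_credibility, update_on_speaker, update_tom,
// novelty, update_on_topic, adapt_scales_and_ledgers, speaker_postprocess).
// The R functions remain the documented reference; an equivalence test
// keeps the two paths in lock-step.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

NumericVector kl_compress_newton(double lx, double l1x, double mu0,
                                 double la0, double tol, int maxit);

static inline double bmean(double mu, double la) {
  return (mu + 1.0) / (mu + la + 2.0);
}

// bounded-confidence safeguard for stored belief exponents: iterated
// compression of conflicting sharp messages can otherwise drive an
// exponent arbitrarily close to -1 (infinite certainty), which is both
// unrealistic and numerically fatal
static const double EXP_FLOOR = -0.999;
static const double EXP_CAP = 1e6;
static inline double clampexp(double x) {
  if (x < EXP_FLOOR) return EXP_FLOOR;
  if (x > EXP_CAP) return EXP_CAP;
  return x;
}

// D_KL(Beta(pm, pl) || Beta(qm, ql)) in exponent form
static inline double klbeta(double pm, double pl, double qm, double ql) {
  double d = R::digamma(pm + pl + 2.0);
  return R::lbeta(qm + 1.0, ql + 1.0) - R::lbeta(pm + 1.0, pl + 1.0) +
         (pm - qm) * (R::digamma(pm + 1.0) - d) +
         (pl - ql) * (R::digamma(pl + 1.0) - d);
}

// two-component compression, exact on degenerate mixtures
// method: 0 = kl_optimal, 1 = moment_matching
static inline void compress_pair(double w, double mu1, double la1,
                                 double mu2, double la2, int method,
                                 double &omu, double &ola) {
  if (w >= 1.0) { omu = mu1; ola = la1; return; }
  if (w <= 0.0) { omu = mu2; ola = la2; return; }
  if (mu1 == mu2 && la1 == la2) { omu = mu1; ola = la1; return; }
  double m1 = (mu1 + 1.0) / (mu1 + la1 + 2.0);
  double m2 = (mu2 + 1.0) / (mu2 + la2 + 2.0);
  double v1 = m1 * (1.0 - m1) / (mu1 + la1 + 3.0);
  double v2 = m2 * (1.0 - m2) / (mu2 + la2 + 3.0);
  double mean = w * m1 + (1.0 - w) * m2;
  double var = w * (v1 + m1 * m1) + (1.0 - w) * (v2 + m2 * m2) - mean * mean;
  double s = mean * (1.0 - mean) / var - 1.0;
  double mmu = mean * s - 1.0;
  double mla = (1.0 - mean) * s - 1.0;
  if (method == 1) { omu = mmu; ola = mla; return; }
  double d1 = R::digamma(mu1 + la1 + 2.0), d2 = R::digamma(mu2 + la2 + 2.0);
  double lx = w * (R::digamma(mu1 + 1.0) - d1) +
              (1.0 - w) * (R::digamma(mu2 + 1.0) - d2);
  double l1x = w * (R::digamma(la1 + 1.0) - d1) +
               (1.0 - w) * (R::digamma(la2 + 1.0) - d2);
  NumericVector r = kl_compress_newton(lx, l1x, mmu, mla, 1e-10, 200);
  omu = r[0]; ola = r[1];
}

// cue codes: 0 none, 1 blush, 2 confession
static inline double credibility(double xbar, double s, bool blush,
                                 bool confession, double kh, double knh,
                                 double eps, int &cue, double &R_) {
  if (blush) { cue = 1; R_ = 0.0; return 0.0; }
  if (confession) { cue = 2; R_ = R_PosInf; return 1.0; }
  cue = 0;
  double logR = std::log(knh) - std::log(kh) + s * (1.0 / knh - 1.0 / kh);
  R_ = std::exp(logR);
  double y = 1.0 / (1.0 + std::exp(-logR) * (1.0 / xbar - 1.0));
  if (y < eps) y = eps;
  if (y > 1.0 - eps) y = 1.0 - eps;
  return y;
}

// Full receiver pipeline for one message, state mutated in place.
// Indices are 1-based agent ids. Returns (y, R, xbar, s_obs, cue).
// [[Rcpp::export]]
NumericVector cpp_receive(NumericMatrix mu, NumericMatrix lam,
                          NumericVector tom_mu, NumericVector tom_lam,
                          NumericVector last_mu, NumericVector last_lam,
                          NumericMatrix rm, NumericMatrix pos,
                          NumericMatrix neg, NumericVector stmt_mean,
                          NumericVector stmt_count, NumericVector kap_h,
                          NumericVector kap_nh, NumericVector kap_lie,
                          int b, int a, int c, double pmu, double pla,
                          bool blush, int method, double eps, double alpha,
                          double floor_, double scale_cap,
                          double novelty_cap) {
  int n = mu.nrow();
  int bi = b - 1, ai = a - 1, ci = c - 1;
  // assess (must see the prior state)
  double xbar = bmean(mu(bi, ai), lam(bi, ai));
  bool conf = !blush && c == a && bmean(pmu, pla) < xbar;
  double s = klbeta(pmu, pla, mu(bi, ci), lam(bi, ci));
  int cue; double R_;
  double y = credibility(xbar, s, blush, conf, kap_h[bi], kap_nh[bi],
                         eps, cue, R_);
  // update belief about the speaker
  double m0 = mu(bi, ai), l0 = lam(bi, ai), nm, nl;
  compress_pair(y, m0 + 1.0, l0, m0, l0 + 1.0, method, nm, nl);
  mu(bi, ai) = clampexp(nm); lam(bi, ai) = clampexp(nl);
  // theory of mind about the speaker's belief on the topic
  R_xlen_t ti = bi + (R_xlen_t)n * (ai + (R_xlen_t)n * ci);
  tom_mu[ti] = y * pmu + (1.0 - y) * tom_mu[ti];
  tom_lam[ti] = y * pla + (1.0 - y) * tom_lam[ti];
  // novelty against the speaker's last statement on the topic
  double prevm = last_mu[ti], prevl = last_lam[ti];
  if (ISNA(prevm)) { prevm = 0.0; prevl = 0.0; }
  double dmu = pmu - prevm; if (dmu < 0.0) dmu = 0.0;
  double dla = pla - prevl; if (dla < 0.0) dla = 0.0;
  double tot = dmu + dla;
  if (tot > novelty_cap) { dmu *= novelty_cap / tot; dla *= novelty_cap / tot; }
  last_mu[ti] = pmu; last_lam[ti] = pla;
  // update belief about the topic
  m0 = mu(bi, ci); l0 = lam(bi, ci);
  compress_pair(y, m0 + dmu, l0 + dla, m0, l0, method, nm, nl);
  mu(bi, ci) = clampexp(nm); lam(bi, ci) = clampexp(nl);
  // adapt surprise scales and ledgers
  double kh = (1.0 - alpha * y) * kap_h[bi] + alpha * y * s;
  double knh = (1.0 - alpha * (1.0 - y)) * kap_nh[bi] + alpha * (1.0 - y) * s;
  if (kh < floor_) kh = floor_;
  if (knh < floor_) knh = floor_;
  kap_h[bi] = (kh > scale_cap) ? scale_cap : kh;
  kap_nh[bi] = (knh > scale_cap) ? scale_cap : knh;
  kap_lie[bi] = kap_h[bi];
  rm(bi, ci) += 1.0;
  if (c == b) {
    double m = bmean(pmu, pla);
    if (m > stmt_mean[bi]) pos(bi, ai) += 1.0; else neg(bi, ai) += 1.0;
    double k = stmt_count[bi];
    stmt_mean[bi] = (stmt_mean[bi] * k + m) / (k + 1.0);
    stmt_count[bi] = k + 1.0;
  }
  return NumericVector::create(y, R_, xbar, s, (double)cue);
}

// Speaker-side theory-of-mind blend after sending, state mutated in place.
// [[Rcpp::export]]
void cpp_speaker_post(NumericVector tom_mu, NumericVector tom_lam,
                      NumericVector kap_h, NumericVector kap_nh,
                      int n, int a, IntegerVector recipients, int c,
                      double pmu, double pla, bool blush, double eps) {
  int ai = a - 1, ci = c - 1;
  for (int j = 0; j < recipients.size(); ++j) {
    int bi = recipients[j] - 1;
    R_xlen_t self_i = ai + (R_xlen_t)n * (bi + (R_xlen_t)n * ai);
    double xbar = bmean(tom_mu[self_i], tom_lam[self_i]);
    bool conf = !blush && c == a && bmean(pmu, pla) < xbar;
    R_xlen_t ti = ai + (R_xlen_t)n * (bi + (R_xlen_t)n * ci);
    double s = klbeta(pmu, pla, tom_mu[ti], tom_lam[ti]);
    int cue; double R_;
    double y = credibility(xbar, s, blush, conf, kap_h[ai], kap_nh[ai],
                           eps, cue, R_);
    tom_mu[ti] = (1.0 - y) * tom_mu[ti] + y * pmu;
    tom_lam[ti] = (1.0 - y) * tom_lam[ti] + y * pla;
  }
}
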