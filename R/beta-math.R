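# Algebra on beta-form belief states: moments, KL divergences, mixtures,
# and the two belief-compression algorithms.

#' Construct a belief state
#'
#' A belief state is a pair of exponents \eqn{(\mu, \lambda)} parameterizing
#' the density \eqn{P(x) \propto x^{\mu}(1-x)^{\lambda}} over an honesty
#' \eqn{x \in (0,1)}, i.e. a beta distribution with shape parameters
#' \eqn{(\mu + 1, \lambda + 1)}. The exponents act as pseudo-counts of honest
#' and dishonest statements. Both may lie anywhere in \eqn{(-1, \infty)}:
#' compressing legitimate mixtures can produce exponents in \eqn{(-1, 0)}, so
#' the domain is deliberately not clamped at zero.
#'
#' @param mu,lam Real exponents, each greater than -1.
#' @return A named numeric vector `c(mu = , lam = )`.
#' @examples
#' belief_state(0, 0)      # the uninformed (uniform) state
#' belief_state(3, 1)      # three honest, one dishonest pseudo-count
#' @export
belief_state <- function(mu, lam) {
  if (!is.numeric(mu) || !is.numeric(lam) || length(mu) != 1L ||
      length(lam) != 1L || !is.finite(mu) || !is.finite(lam))
    stop("belief exponents must be single finite numbers")
  if (mu <= -1 || lam <= -1)
    stop("belief exponents must be > -1 (density not normalizable)")
  c(mu = mu, lam = lam)
}

#' Mean of a beta-form belief state
#'
#' @param mu,lam Belief exponents (vectorized).
#' @return `(mu + 1) / (mu + lam + 2)`, the expected honesty.
#' @export
beta_mean <- function(mu, lam) (mu + 1) / (mu + lam + 2)

#' Variance of a beta-form belief state
#'
#' @param mu,lam Belief exponents (vectorized).
#' @return `mean * (1 - mean) / (mu + lam + 3)`.
#' @export
beta_variance <- function(mu, lam) {
  m <- beta_mean(mu, lam)
  m * (1 - m) / (mu + lam + 3)
}

#' Logarithmic moments of a beta-form belief state
#'
#' The expectations of `ln(x)` and `ln(1 - x)`, both strictly negative.
#' These are the two moments conserved by KL-optimal compression.
#'
#' @param mu,lam Belief exponents (vectorized).
#' @return A list with components `ln_x` and `ln_1mx`:
#'   `ln_x = digamma(mu + 1) - digamma(mu + lam + 2)` and
#'   `ln_1mx = digamma(lam + 1) - digamma(mu + lam + 2)`.
#' @export
beta_log_moments <- function(mu, lam) {
  d <- digamma(mu + lam + 2)
  list(ln_x = digamma(mu + 1) - d, ln_1mx = digamma(lam + 1) - d)
}

#' Kullback-Leibler divergence between two belief states
#'
#' Closed-form `D_KL(Beta(p) || Beta(q))` for belief states in exponent form.
#' Nonnegative, zero iff the states coincide, and asymmetric in general.
#'
#' @param p,q Belief states, numeric length-2 `(mu, lam)`.
#' @return The divergence in nats.
#' @export
kl_beta <- function(p, q) {
  lp <- beta_log_moments(p[[1L]], p[[2L]])
  lbeta(q[[1L]] + 1, q[[2L]] + 1) - lbeta(p[[1L]] + 1, p[[2L]] + 1) +
    (p[[1L]] - q[[1L]]) * lp$ln_x + (p[[2L]] - q[[2L]]) * lp$ln_1mx
}

#' Construct a two-component belief mixture
#'
#' The posterior form arising from an uncertain message: with probability
#' `weight_h` (the credibility) the message was honest and the state is
#' `comp_h`, otherwise `comp_nh`.
#'
#' @param weight_h Probability in `[0, 1]` that the honest branch holds.
#' @param comp_h,comp_nh Belief states (length-2 numeric `(mu, lam)`).
#' @return An object of class `rg_mixture`.
#' @export
mixture_belief <- function(weight_h, comp_h, comp_nh) {
  if (!is.numeric(weight_h) || length(weight_h) != 1L ||
      weight_h < 0 || weight_h > 1)
    stop("weight_h must be a probability in [0, 1]")
  stopifnot(length(comp_h) == 2L, length(comp_nh) == 2L)
  if (any(c(comp_h, comp_nh) <= -1))
    stop("component exponents must be > -1")
  structure(list(w = as.numeric(weight_h),
                 h = as.numeric(comp_h), nh = as.numeric(comp_nh)),
            class = "rg_mixture")
}

#' Mean and variance of a belief mixture
#'
#' Uses the standard mixture identities: the mean is the weighted component
#' mean, the second moment is the weighted component second moment, and the
#' variance follows as `E[x^2] - E[x]^2`.
#'
#' @param m An `rg_mixture`.
#' @return Named numeric vector `c(mean = , variance = )`.
#' @export
mixture_moments <- function(m) {
  m1 <- beta_mean(m$h[1L], m$h[2L]);  v1 <- beta_variance(m$h[1L], m$h[2L])
  m2 <- beta_mean(m$nh[1L], m$nh[2L]); v2 <- beta_variance(m$nh[1L], m$nh[2L])
  mean <- m$w * m1 + (1 - m$w) * m2
  ex2 <- m$w * (v1 + m1^2) + (1 - m$w) * (v2 + m2^2)
  c(mean = mean, variance = ex2 - mean^2)
}

# Core compression of an N-component beta mixture into a single belief state.
# weights need not be normalized; zero-weight components are dropped and a
# degenerate (single-component) mixture is returned exactly.
# method: "kl_optimal" conserves <ln x>, <ln(1-x)> (digamma Newton solve);
#         "moment_matching" conserves mean and variance (analytic inversion).
.compress_mix <- function(w, mus, lams, method) {
  keep <- w > 0
  w <- w[keep]; mus <- mus[keep]; lams <- lams[keep]
  if (length(w) == 0L) stop("mixture has no support")
  w <- w / sum(w)
  if (length(w) == 1L || (all(mus == mus[1L]) && all(lams == lams[1L])))
    return(c(mus[1L], lams[1L]))
  m <- beta_mean(mus, lams)
  v <- beta_variance(mus, lams)
  mean <- sum(w * m)
  var <- sum(w * (v + m^2)) - mean^2
  if (var <= 0 || var >= mean * (1 - mean))
    stop("mixture variance outside (0, mean*(1-mean)); no beta state exists")
  # moment-matching inversion; also the Newton initialization for KL
  s <- mean * (1 - mean) / var - 1
  mm <- c(mean * s - 1, (1 - mean) * s - 1)
  if (method == "moment_matching") return(mm)
  d <- digamma(mus + lams + 2)
  lx <- sum(w * (digamma(mus + 1) - d))
  l1x <- sum(w * (digamma(lams + 1) - d))
  kl_compress_newton(lx, l1x, mm[1L], mm[2L])
}

#' Moment-matching belief compression
#'
#' Compresses a two-component belief mixture into the unique single beta-form
#' state with the same mean and variance (reputation-conserving compression).
#' Inverts mean/variance to exponents via
#' `s = mean(1-mean)/variance - 1`, `mu = mean*s - 1`, `lam = (1-mean)*s - 1`.
#' A degenerate mixture (weight 0 or 1, or identical components) is returned
#' exactly.
#'
#' @param m An `rg_mixture`.
#' @return A belief state `c(mu, lam)` whose [beta_mean()] and
#'   [beta_variance()] equal [mixture_moments()] of the input.
#' @export
compress_moment_matching <- function(m) {
  .compress_mix(c(m$w, 1 - m$w), c(m$h[1L], m$nh[1L]), c(m$h[2L], m$nh[2L]),
                "moment_matching")
}

#' KL-optimal belief compression
#'
#' Compresses a two-component belief mixture into the single beta-form state
#' minimizing the Kullback-Leibler divergence from the mixture, which is
#' equivalent to conserving the logarithmic moments `<ln x>` and
#' `<ln(1 - x)>`. The mixture log-moments are the credibility-weighted sums
#' of the component closed forms; the digamma system is inverted by a damped
#' Newton iteration initialized at the moment-matching solution (residual
#' tolerance 1e-10, at most 200 iterations; non-convergence is an error).
#'
#' @param m An `rg_mixture`.
#' @return A belief state `c(mu, lam)` with the mixture's log-moments.
#' @export
compress_kl_optimal <- function(m) {
  .compress_mix(c(m$w, 1 - m$w), c(m$h[1L], m$nh[1L]), c(m$h[2L], m$nh[2L]),
                "kl_optimal")
}

#' Compress a general weighted beta mixture
#'
#' N-component generalization used e.g. to merge an audience's estimated
#' opinions into one state before targeting a lie.
#'
#' @param weights Nonnegative weights (normalized internally).
#' @param mus,lams Component exponent vectors.
#' @param method `"kl_optimal"` or `"moment_matching"`.
#' @return A belief state `c(mu, lam)`.
#' @export
compress_mixture <- function(weights, mus, lams,
                             method = c("kl_optimal", "moment_matching")) {
  method <- match.arg(method)
  stopifnot(length(weights) == length(mus), length(mus) == length(lams),
            all(weights >= 0))
  .compress_mix(weights, mus, lams, method)
}

# Fast two-component compression used in the reception hot path; bypasses
# the mixture constructor. Exact for degenerate weights.
.compress_pair <- function(w, mu1, la1, mu2, la2, method) {
  if (w >= 1) return(c(mu1, la1))
  if (w <= 0) return(c(mu2, la2))
  if (mu1 == mu2 && la1 == la2) return(c(mu1, la1))
  m1 <- (mu1 + 1) / (mu1 + la1 + 2)
  m2 <- (mu2 + 1) / (mu2 + la2 + 2)
  v1 <- m1 * (1 - m1) / (mu1 + la1 + 3)
  v2 <- m2 * (1 - m2) / (mu2 + la2 + 3)
  mean <- w * m1 + (1 - w) * m2
  var <- w * (v1 + m1^2) + (1 - w) * (v2 + m2^2) - mean^2
  s <- mean * (1 - mean) / var - 1
  mmu <- mean * s - 1
  mla <- (1 - mean) * s - 1
  if (method == "moment_matching") return(c(mmu, mla))
  d1 <- digamma(mu1 + la1 + 2); d2 <- digamma(mu2 + la2 + 2)
  lx <- w * (digamma(mu1 + 1) - d1) + (1 - w) * (digamma(mu2 + 1) - d2)
  l1x <- w * (digamma(la1 + 1) - d1) + (1 - w) * (digamma(la2 + 1) - d2)
  kl_compress_newton(lx, l1x, mmu, mla)
}
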