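# Independent numerical oracles: midpoint-grid quadrature over (0,1) and a
# brute-force Nelder-Mead KL minimizer. These never call the closed forms
# they are used to check.

quad_x <- (seq_len(1e4) - 0.5) / 1e4
quad_dx <- 1e-4

beta_pdf <- function(x, mu, lam) {
  exp(mu * log(x) + lam * log(1 - x) - lbeta(mu + 1, lam + 1))
}

mix_pdf <- function(x, m) {
  m$w * beta_pdf(x, m$h[1], m$h[2]) + (1 - m$w) * beta_pdf(x, m$nh[1], m$nh[2])
}

quad_beta_mean <- function(mu, lam) sum(quad_x * beta_pdf(quad_x, mu, lam)) * quad_dx

quad_beta_var <- function(mu, lam) {
  m <- quad_beta_mean(mu, lam)
  sum((quad_x - m)^2 * beta_pdf(quad_x, mu, lam)) * quad_dx
}

quad_log_moments <- function(mu, lam) {
  p <- beta_pdf(quad_x, mu, lam)
  c(sum(log(quad_x) * p), sum(log(1 - quad_x) * p)) * quad_dx
}

# KL of one beta against another by quadrature
quad_kl_beta <- function(p, q) {
  fp <- beta_pdf(quad_x, p[1], p[2])
  fq <- beta_pdf(quad_x, q[1], q[2])
  sum(fp * log(fp / fq)) * quad_dx
}

# KL of a two-component mixture against a candidate beta by quadrature
quad_kl_mix <- function(m, cand) {
  fm <- mix_pdf(quad_x, m)
  fq <- beta_pdf(quad_x, cand[1], cand[2])
  sum(fm * log(fm / fq)) * quad_dx
}

# brute-force KL-optimal compression: Nelder-Mead on the quadrature
# objective, started from a neutral point well away from the solution
oracle_kl_compress <- function(m) {
  fit <- optim(c(1, 1), function(p) {
    if (any(p <= -0.99)) return(1e10)
    quad_kl_mix(m, p)
  }, method = "Nelder-Mead",
  control = list(maxit = 2000, reltol = 1e-12))
  fit$par
}

random_mixture <- function() {
  mixture_belief(runif(1, 0.05, 0.95),
                 c(runif(1, 0, 20), runif(1, 0, 20)),
                 c(runif(1, 0, 20), runif(1, 0, 20)))
}

# a small population with hand-settable ledgers for sampling tests
fresh_pop <- function(n, seed = 1, ...) init_population(n, seed = seed, ...)
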