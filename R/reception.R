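# Receiver side: credibility judgment with blush/confession/surprise cues,
# the three knowledge updates with compression, novelty filtering, ledger
# updates, and surprise-scale adaptation.

# Core credibility rule. Cues override everything: a blush is a certain
# dishonesty signal (y = 0), a confession a certain honesty signal (y = 1).
# Otherwise Bayes with the speaker's reputation xbar as prior and the
# likelihood ratio of the observed surprise s under exponential surprise
# models with the receiver's learned honest/dishonest scales:
#   R(s) = [kh^-1 exp(-s/kh)] / [knh^-1 exp(-s/knh)]
#   y = 1 / (1 + (1/xbar - 1) / R),   clipped to [eps, 1 - eps].
# R reduces to 1 (y = xbar) when the two scales coincide.
.credibility <- function(xbar, s, blush, confession, kh, knh, eps) {
  if (blush) return(list(y = 0, R = 0, cue = "blush"))
  if (confession) return(list(y = 1, R = Inf, cue = "confession"))
  logR <- log(knh) - log(kh) + s * (1 / knh - 1 / kh)
  # y = 1 / (1 + exp(-logR) * (1/xbar - 1)), computed stably in logs
  y <- 1 / (1 + exp(-logR) * (1 / xbar - 1))
  y <- min(max(y, eps), 1 - eps)
  list(y = y, R = exp(logR), cue = "none")
}

#' Judge the credibility of a received message
#'
#' Estimates the probability that the message was honest. The receiver's
#' expected honesty of the speaker acts as the Bayesian prior; telltale
#' cues override the inference (blush: certainly dishonest; confession: a
#' self-referential message more negative than the receiver's current view
#' of the speaker, certainly honest); otherwise the likelihood ratio of the
#' observed surprise (KL divergence of the payload from the receiver's
#' prior belief about the topic) under the receiver's learned honest and
#' dishonest surprise scales is combined with the prior.
#'
#' @param pop An `rg_population`.
#' @param b Receiving agent index.
#' @param msg A message from [construct_message()].
#' @return A list with `credibility` (y), `likelihood_ratio`,
#'   `speaker_reputation`, `surprise_observed`, `cue`
#'   (`"none"`, `"blush"`, or `"confession"`).
#' @export
assess_credibility <- function(pop, b, msg) {
  a <- msg$speaker; cc <- msg$topic
  xbar <- beta_mean(pop$mu[b, a], pop$lam[b, a])
  conf <- !msg$blush && cc == a &&
    beta_mean(msg$mu, msg$lam) < xbar
  s <- kl_beta(c(msg$mu, msg$lam), c(pop$mu[b, cc], pop$lam[b, cc]))
  cr <- .credibility(xbar, s, msg$blush, conf,
                     pop$kap_h[b], pop$kap_nh[b], pop$const$epsilon)
  list(credibility = cr$y, likelihood_ratio = cr$R,
       speaker_reputation = xbar, surprise_observed = s, cue = cr$cue)
}

#' Update the receiver's belief about the speaker
#'
#' The posterior is the credibility-weighted mixture of "one more honest
#' statement" `(mu + 1, lam)` and "one more dishonest statement"
#' `(mu, lam + 1)`, compressed back into a single belief state with the
#' population's configured compression.
#'
#' @param pop An `rg_population`.
#' @param b Receiving agent index.
#' @param a Speaker index.
#' @param y Credibility in `[0, 1]`.
#' @return The new belief state `c(mu, lam)` (also stored in place).
#' @export
update_on_speaker <- function(pop, b, a, y) {
  mu <- pop$mu[b, a]; la <- pop$lam[b, a]
  st <- .clamp_state(.compress_pair(y, mu + 1, la, mu, la + 1,
                                    pop$compression))
  pop$mu[b, a] <- st[1L]
  pop$lam[b, a] <- st[2L]
  st
}

# bounded-confidence safeguard for stored belief exponents (matches the
# C++ engine path): agents can never become infinitely certain
.clamp_state <- function(st) pmin(pmax(st, -0.999), 1e6)

#' Update the receiver's theory of mind about the speaker's belief
#'
#' DeGroot-style blend: the stored estimate of the speaker's belief about
#' the topic moves toward the payload with weight equal to the credibility.
#' No compression is needed since the blend is already a single state.
#'
#' @param pop An `rg_population`.
#' @param b Receiving agent index.
#' @param a Speaker index.
#' @param cc Topic index.
#' @param y Credibility.
#' @param payload Message belief state `c(mu, lam)`.
#' @return The new theory-of-mind entry `c(mu, lam)` (stored in place).
#' @export
update_tom <- function(pop, b, a, cc, y, payload) {
  mu <- y * payload[1L] + (1 - y) * pop$tom_mu[b, a, cc]
  la <- y * payload[2L] + (1 - y) * pop$tom_lam[b, a, cc]
  pop$tom_mu[b, a, cc] <- mu
  pop$tom_lam[b, a, cc] <- la
  c(mu, la)
}

#' Novelty of a message relative to the speaker's last statement
#'
#' Componentwise clipped difference between the payload and the most recent
#' message from the same speaker on the same topic (taken as the uniform
#' state `(0, 0)` if none was heard before). Repeating the same opinion
#' carries no new information. The last-heard ledger is updated to the
#' payload.
#'
#' @param pop An `rg_population`.
#' @param b Receiving agent index.
#' @param a Speaker index.
#' @param cc Topic index.
#' @param payload Message belief state `c(mu, lam)`.
#' @return Nonnegative increment `c(d_mu, d_lam)`.
#' @export
novelty <- function(pop, b, a, cc, payload) {
  pm <- pop$last_mu[b, a, cc]
  pl <- pop$last_lam[b, a, cc]
  if (is.na(pm)) { pm <- 0; pl <- 0 }
  inc <- c(max(0, payload[1L] - pm), max(0, payload[2L] - pl))
  # one statement carries at most novelty_cap observations' worth of
  # evidence; scale down preserving the honest/dishonest direction
  tot <- inc[1L] + inc[2L]
  if (tot > pop$const$novelty_cap) inc <- inc * (pop$const$novelty_cap / tot)
  pop$last_mu[b, a, cc] <- payload[1L]
  pop$last_lam[b, a, cc] <- payload[2L]
  inc
}

#' Update the receiver's belief about the topic
#'
#' The posterior is the credibility-weighted mixture of "accept the novel
#' part of the message" `(mu + d_mu, lam + d_lam)` and "ignore it"
#' `(mu, lam)`, compressed into a single belief state. Self-topic messages
#' update the receiver's self-esteem through the same rule.
#'
#' @param pop An `rg_population`.
#' @param b Receiving agent index.
#' @param cc Topic index.
#' @param y Credibility.
#' @param inc Novelty increment `c(d_mu, d_lam)` from [novelty()].
#' @return The new belief state `c(mu, lam)` (stored in place).
#' @export
update_on_topic <- function(pop, b, cc, y, inc) {
  mu <- pop$mu[b, cc]; la <- pop$lam[b, cc]
  st <- .clamp_state(.compress_pair(y, mu + inc[1L], la + inc[2L], mu, la,
                                    pop$compression))
  pop$mu[b, cc] <- st[1L]
  pop$lam[b, cc] <- st[2L]
  st
}

#' Realized surprise of a credibility judgment
#'
#' The KL divergence between the true (degenerate) honesty status of a
#' message and the receiver's assigned distribution `(y, 1 - y)`:
#' `-ln(y)` if the message was actually honest, `-ln(1 - y)` otherwise.
#' Instrumentation only; ground truth is never fed back into agent state.
#'
#' @param y Credibility assigned by the receiver.
#' @param actually_honest Logical ground truth.
#' @return Nonnegative surprise in nats.
#' @export
record_surprise <- function(y, actually_honest) {
  if (actually_honest) -log(y) else -log(1 - y)
}

#' Adapt surprise scales and bookkeeping ledgers after a message
#'
#' The honest and dishonest surprise scales are exponential moving averages
#' of the credibility-weighted observed surprise (floored at a small
#' positive constant); the lie-sizing scale tracks the honest scale (the
#' perceived social climate). The messages-heard counter for the topic is
#' incremented, and if the topic is the receiver itself the statement is
#' classified as comparatively positive or negative against the running
#' mean of statement means heard about oneself, feeding the friendship
#' ledger.
#'
#' @param pop An `rg_population`.
#' @param b Receiving agent index.
#' @param msg The message.
#' @param assessment Result of [assess_credibility()].
#' @return The population, invisibly (state updated in place).
#' @export
adapt_scales_and_ledgers <- function(pop, b, msg, assessment) {
  al <- pop$const$ema_alpha
  fl <- pop$const$scale_floor
  y <- assessment$credibility
  s <- assessment$surprise_observed
  # credibility-weighted-rate EMA: each scale moves toward the observed
  # surprise at a rate proportional to the evidence for its hypothesis, so
  # a message judged dishonest leaves the honest scale (almost) untouched
  cp <- pop$const$scale_cap
  pop$kap_h[b] <- min(cp, max(fl, (1 - al * y) * pop$kap_h[b] + al * y * s))
  pop$kap_nh[b] <- min(cp, max(fl, (1 - al * (1 - y)) * pop$kap_nh[b] +
                                 al * (1 - y) * s))
  pop$kap_lie[b] <- pop$kap_h[b]
  cc <- msg$topic
  pop$rm[b, cc] <- pop$rm[b, cc] + 1
  if (cc == b) {
    m <- beta_mean(msg$mu, msg$lam)
    a <- msg$speaker
    if (m > pop$stmt_mean[b]) {
      pop$pos[b, a] <- pop$pos[b, a] + 1
    } else {
      pop$neg[b, a] <- pop$neg[b, a] + 1
    }
    k <- pop$stmt_count[b]
    pop$stmt_mean[b] <- (pop$stmt_mean[b] * k + m) / (k + 1)
    pop$stmt_count[b] <- k + 1
  }
  invisible(pop)
}

#' Process one received message
#'
#' Runs the full receiver pipeline in its fixed order: assess credibility,
#' update belief about the speaker, update theory of mind, filter novelty,
#' update belief about the topic, adapt scales and ledgers. The order
#' matters: the assessment must see the prior state.
#'
#' @param pop An `rg_population`.
#' @param b Receiving agent index.
#' @param msg A message.
#' @return The assessment (list), with `realized_surprise` added.
#' @export
receive_message <- function(pop, b, msg) {
  if (isTRUE(pop$use_cpp)) {
    out <- cpp_receive(pop$mu, pop$lam, pop$tom_mu, pop$tom_lam,
                       pop$last_mu, pop$last_lam, pop$rm, pop$pos, pop$neg,
                       pop$stmt_mean, pop$stmt_count, pop$kap_h, pop$kap_nh,
                       pop$kap_lie, b, msg$speaker, msg$topic, msg$mu,
                       msg$lam, msg$blush,
                       if (pop$compression == "moment_matching") 1L else 0L,
                       pop$const$epsilon, pop$const$ema_alpha,
                       pop$const$scale_floor, pop$const$scale_cap,
                       pop$const$novelty_cap)
    as_ <- list(credibility = out[1L], likelihood_ratio = out[2L],
                speaker_reputation = out[3L], surprise_observed = out[4L],
                cue = c("none", "blush", "confession")[out[5L] + 1])
    as_$realized_surprise <- record_surprise(out[1L], msg$honest)
    return(as_)
  }
  as_ <- assess_credibility(pop, b, msg)
  y <- as_$credibility
  update_on_speaker(pop, b, msg$speaker, y)
  payload <- c(msg$mu, msg$lam)
  update_tom(pop, b, msg$speaker, msg$topic, y, payload)
  inc <- novelty(pop, b, msg$speaker, msg$topic, payload)
  update_on_topic(pop, b, msg$topic, y, inc)
  adapt_scales_and_ledgers(pop, b, msg, as_)
  as_$realized_surprise <- record_surprise(y, msg$honest)
  as_
}
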