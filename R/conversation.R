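# Speaker side: choose recipients and topic, decide honesty, and construct
# the message (including audience-targeted lies).

# sample one element of idx with weights w (handles length-1 idx safely)
.sample1 <- function(idx, w) {
  if (length(idx) == 1L) return(idx)
  idx[sample.int(length(idx), 1L, prob = w)]
}

# sample k distinct elements of idx with weights w (sequential weighted
# sampling without replacement); pads zero weights uniformly if the support
# is smaller than k
.sample_k <- function(idx, w, k) {
  if (sum(w > 0) < k) w <- w + max(w, 1) * 1e-12
  idx[sample.int(length(idx), k, prob = w, replace = FALSE)]
}

# Partner-choice weights of initiator a over all agents:
# w_b ∝ r_ab^S_a * f_ab^F_a, zero for a itself. 0^0 == 1, so a fully
# extroverted agent (S = F = 0) weights everyone equally from round one.
.partner_weights <- function(pop, a) {
  if (!pop$track_acquaintance) {
    w <- rep(1, pop$n)
  } else {
    r <- pop$rm[a, ] + pop$const$Q * pop$rc[a, ]
    f <- (pop$pos[a, ] + 1) / (pop$pos[a, ] + pop$neg[a, ] + 2)
    w <- r^pop$shyness[a] * f^pop$friendship_affinity[a]
  }
  w[a] <- 0
  w
}

#' Choose the recipients of a conversation
#'
#' The initiator first decides (fair coin, see `one_to_many_prob`) between a
#' one-to-one conversation (which will be answered) and a one-to-many
#' broadcast (one-way). A single partner is sampled with probability
#' proportional to `r_ab^S_a * f_ab^F_a`; for a broadcast the audience size
#' `N_b` is drawn from `P(N_b) \propto N_b^{-S_a}` over `2..(n-1)` and then
#' `N_b` distinct recipients are sampled from the same partner weights.
#' When all weights vanish (cold start: no acquaintance yet and `S_a > 0`)
#' the choice falls back to uniform.
#'
#' @param pop An `rg_population`.
#' @param a Initiating agent index.
#' @return A list (conversation plan) with `initiator`, `recipients`,
#'   `mode` (`"one_to_one"` or `"one_to_many"`).
#' @export
choose_recipients <- function(pop, a) {
  n <- pop$n
  many <- n >= 3 && runif(1) < pop$const$one_to_many_prob
  others <- seq_len(n)[-a]
  w <- .partner_weights(pop, a)[others]
  if (sum(w) == 0) w <- rep(1, n - 1)
  if (!many) {
    list(initiator = a, recipients = .sample1(others, w), mode = "one_to_one")
  } else {
    sizes <- 2:(n - 1)
    nb <- if (length(sizes) == 1L) sizes else
      .sample1(sizes, sizes^(-pop$shyness[a]))
    list(initiator = a, recipients = .sample_k(others, w, nb),
         mode = "one_to_many")
  }
}

#' Choose a conversation topic
#'
#' The topic (an agent, possibly the initiator itself) is sampled with
#' probability proportional to the initiator's acquaintance with it raised
#' to the shyness, `r_ac^S_a`, so agents talk about agents they actually
#' have information on. Cold start falls back to uniform.
#'
#' @param pop An `rg_population`.
#' @param a Initiating agent index.
#' @param plan Conversation plan from [choose_recipients()] (unused for the
#'   weights; kept for interface symmetry).
#' @return The topic agent index.
#' @export
choose_topic <- function(pop, a, plan = NULL) {
  n <- pop$n
  if (!pop$track_acquaintance) {
    w <- rep(1, n)
  } else {
    r <- pop$rm[a, ] + pop$const$Q * pop$rc[a, ]
    w <- r^pop$shyness[a]
  }
  if (sum(w) == 0) w <- rep(1, n)
  .sample1(seq_len(n), w)
}

#' Decide whether a statement is honest
#'
#' Bernoulli draw with the speaker's intrinsic honesty, independently per
#' statement (the answer in a conversation draws afresh).
#'
#' @param pop An `rg_population`.
#' @param a Speaking agent index.
#' @return Logical.
#' @export
decide_honest <- function(pop, a) runif(1) < pop$honesty[a]

#' Merge the audience's estimated opinions about a topic
#'
#' For a broadcast lie the speaker targets the socially accepted group
#' opinion: the weighted superposition of its theory-of-mind estimates of
#' each recipient's belief about the topic, with the partner-choice weights
#' `w_i \propto r_ai^S_a * f_ai^F_a`, compressed into a single belief state
#' with the population's configured compression. A single recipient yields
#' that recipient's theory-of-mind entry exactly.
#'
#' @param pop An `rg_population`.
#' @param a Speaking agent index.
#' @param recipients Recipient indices.
#' @param topic Topic agent index.
#' @return A list with `weights` (normalized, named by recipient) and
#'   `opinion` (a belief state `c(mu, lam)`).
#' @export
merge_audience_opinion <- function(pop, a, recipients, topic) {
  if (length(recipients) == 1L) {
    return(list(weights = setNames(1, recipients),
                opinion = c(pop$tom_mu[a, recipients, topic],
                            pop$tom_lam[a, recipients, topic])))
  }
  w <- .partner_weights(pop, a)[recipients]
  if (sum(w) == 0) w <- rep(1, length(recipients))
  w <- w / sum(w)
  op <- .compress_mix(w, pop$tom_mu[a, recipients, topic],
                      pop$tom_lam[a, recipients, topic], pop$compression)
  list(weights = setNames(w, recipients), opinion = op)
}

#' Construct a message
#'
#' Honest statements transmit the speaker's own belief about the topic
#' verbatim. A lie starts from the (merged) theory-of-mind estimate of the
#' audience's opinion so as to stay believable, then shifts it: positively
#' (in the `mu` exponent) if the speaker regards the topic a friend
#' (`f_ac > 1/2`) or the topic is the speaker itself (self-promotion,
#' pretending `f = 1`), negatively (in `lam`) for an enemy (`f_ac < 1/2`),
#' and not at all for `f_ac = 1/2` (a white lie). The raw shift is sized so
#' that the shifted state diverges from the base by the speaker's learned
#' lie scale (the social climate, in nats) and is then scaled by `|2f - 1|`.
#' Each lie independently blushes with probability `blush_rate`.
#'
#' @param pop An `rg_population`.
#' @param a Speaking agent index.
#' @param plan Conversation plan (needs `recipients`); `topic` is passed
#'   separately.
#' @param topic Topic agent index.
#' @param honest Logical from [decide_honest()].
#' @return A message: list with `speaker`, `topic`, `recipients`, `mu`,
#'   `lam`, `honest`, `blush`.
#' @export
construct_message <- function(pop, a, plan, topic, honest) {
  if (honest) {
    payload <- c(pop$mu[a, topic], pop$lam[a, topic])
    blush <- FALSE
  } else {
    base <- merge_audience_opinion(pop, a, plan$recipients, topic)$opinion
    f <- friendship(pop, a, topic)
    if (a == topic || f > 0.5) {
      factor <- if (a == topic) 1 else abs(2 * f - 1)
      if (factor > 0) {
        d <- lie_delta(base[1L], base[2L], pop$kap_lie[a])
        payload <- c(base[1L] + factor * d, base[2L])
      } else payload <- base
    } else if (f < 0.5) {
      factor <- abs(2 * f - 1)
      # lambda shift: mirror symmetry x -> 1-x swaps the exponent roles
      d <- lie_delta(base[2L], base[1L], pop$kap_lie[a])
      payload <- c(base[1L], base[2L] + factor * d)
    } else {
      payload <- base  # white lie
    }
    blush <- runif(1) < pop$const$blush_rate
  }
  list(speaker = a, topic = topic, recipients = plan$recipients,
       mu = payload[1L], lam = payload[2L], honest = honest, blush = blush)
}

#' Speaker-side bookkeeping after sending a message
#'
#' For every recipient the speaker predicts, from its own theory-of-mind
#' quantities and surprise scales, the credibility the recipient will assign
#' to the message, and blends its theory-of-mind entry for (recipient,
#' topic) toward the sent payload with that predicted weight.
#'
#' @param pop An `rg_population`.
#' @param msg A message from [construct_message()].
#' @return The population, invisibly (state updated in place).
#' @export
speaker_postprocess <- function(pop, msg) {
  if (isTRUE(pop$use_cpp)) {
    cpp_speaker_post(pop$tom_mu, pop$tom_lam, pop$kap_h, pop$kap_nh,
                     pop$n, msg$speaker, as.integer(msg$recipients),
                     msg$topic, msg$mu, msg$lam, msg$blush,
                     pop$const$epsilon)
    return(invisible(pop))
  }
  a <- msg$speaker; cc <- msg$topic
  for (b in msg$recipients) {
    # speaker's estimate of its own reputation in b's eyes
    xbar <- beta_mean(pop$tom_mu[a, b, a], pop$tom_lam[a, b, a])
    conf <- !msg$blush && cc == a &&
      beta_mean(msg$mu, msg$lam) < xbar
    s <- kl_beta(c(msg$mu, msg$lam),
                 c(pop$tom_mu[a, b, cc], pop$tom_lam[a, b, cc]))
    y <- .credibility(xbar, s, msg$blush, conf,
                      pop$kap_h[a], pop$kap_nh[a], pop$const$epsilon)$y
    pop$tom_mu[a, b, cc] <- (1 - y) * pop$tom_mu[a, b, cc] + y * msg$mu
    pop$tom_lam[a, b, cc] <- (1 - y) * pop$tom_lam[a, b, cc] + y * msg$lam
  }
  invisible(pop)
}
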