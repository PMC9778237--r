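# Per-agent hidden traits, belief stores, theory of mind, and bookkeeping
# ledgers. The population is held in an environment so that the simulation
# engine can update state in place.

#' Behavioral constants of a simulation
#'
#' @param Q Weight of a conversation relative to a heard message in the
#'   acquaintance count `r_ab = r_m + Q * r_c`. Default 10.
#' @param blush_rate Probability that a lie is accompanied by a blush
#'   (a certain dishonesty signal). Default 0.1, i.e. every 10th lie.
#' @param ema_alpha Exponential-moving-average constant for the adaptive
#'   surprise scales (the perceived social climate). Default 0.1.
#' @param epsilon Clipping bound keeping cue-free credibilities inside
#'   `[epsilon, 1 - epsilon]` so recorded surprises stay finite.
#' @param initial_scale Initial value (nats) of all surprise scales.
#' @param scale_floor Lower floor for surprise scales.
#' @param scale_cap Upper cap for surprise scales (nats). Bounds the social
#'   climate: without it the typical-surprise scales track the unbounded
#'   disagreement divergences of ever-sharpening beliefs and the lie sizes
#'   they set diverge with them.
#' @param novelty_cap Maximum total pseudo-count weight a single message can
#'   contribute to the receiver's topic belief (the novelty increment is
#'   scaled down to this total if it exceeds it, preserving its direction).
#'   One statement is at most `novelty_cap` observations' worth of
#'   evidence; without the cap, sharp payloads echo through the group and
#'   inflate everyone's pseudo-counts exponentially.
#' @param one_to_many_prob Probability that an initiated conversation is a
#'   one-to-many broadcast rather than a one-to-one exchange.
#' @return A named list of constants.
#' @export
rg_constants <- function(Q = 10, blush_rate = 0.1, ema_alpha = 0.1,
                         epsilon = 1e-6, initial_scale = 1,
                         scale_floor = 1e-3, scale_cap = 100,
                         novelty_cap = 10, one_to_many_prob = 0.5) {
  stopifnot(Q >= 0, blush_rate >= 0, blush_rate <= 1,
            ema_alpha > 0, ema_alpha <= 1, epsilon > 0, epsilon < 0.5,
            initial_scale > 0, scale_floor > 0, scale_cap > scale_floor,
            novelty_cap > 0,
            one_to_many_prob >= 0, one_to_many_prob <= 1)
  list(Q = Q, blush_rate = blush_rate, ema_alpha = ema_alpha,
       epsilon = epsilon, initial_scale = initial_scale,
       scale_floor = scale_floor, scale_cap = scale_cap,
       novelty_cap = novelty_cap, one_to_many_prob = one_to_many_prob)
}

#' Initialize a population of agents
#'
#' Creates the full mutable state of one simulation realization: hidden
#' traits, belief books, theory of mind, and all ledgers. Agents start
#' knowing nothing: every belief and every theory-of-mind entry is the
#' uniform state `(0, 0)` (mean 0.5), all counters are zero, and the
#' surprise scales sit at their configured initial value.
#'
#' Hidden traits: honesty is either an even grid `i/(n-1)` spanning
#' `[0, 1]` (the default) or an explicit vector; friendship affinity is
#' drawn uniformly on `[0, 1]` and shyness uniformly on `[0, 2]`. The
#' shyness range extends into the superlinear regime because partner
#' choice weights acquaintance as `r^S`: sublinear reinforcement (S < 1)
#' cannot condense onto a few favorite partners, and the emergent small
#' conversation groups require condensation.
#'
#' @param n Number of agents (at least 2).
#' @param honesty `NULL` for the even grid, or a numeric vector of length
#'   `n` with values in `[0, 1]`.
#' @param seed Optional integer seed applied before trait draws.
#' @param compression `"kl_optimal"` or `"moment_matching"`; the belief
#'   compression used by every agent on both the speaker and receiver side.
#' @param track_acquaintance If `FALSE`, partner and topic choice ignore the
#'   acquaintance and friendship ledgers and are uniform (the small-group
#'   mode used in the three-agent comparison experiment).
#' @param constants See [rg_constants()].
#' @return An environment of class `rg_population`.
#' @export
init_population <- function(n, honesty = NULL, seed = NULL,
                            compression = c("kl_optimal", "moment_matching"),
                            track_acquaintance = TRUE,
                            constants = rg_constants()) {
  compression <- match.arg(compression)
  if (!is.numeric(n) || length(n) != 1L || n < 2)
    stop("need at least 2 agents")
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(honesty)) {
    honesty <- (seq_len(n) - 1) / (n - 1)
  } else {
    if (length(honesty) != n || any(!is.finite(honesty)) ||
        any(honesty < 0 | honesty > 1))
      stop("explicit honesty list must have length n with values in [0, 1]")
    honesty <- as.numeric(honesty)
  }
  pop <- new.env(parent = emptyenv())
  pop$n <- n
  pop$honesty <- honesty
  pop$shyness <- runif(n, 0, 2)
  pop$friendship_affinity <- runif(n)
  pop$compression <- compression
  pop$track_acquaintance <- isTRUE(track_acquaintance)
  pop$const <- constants
  # belief book: mu[i, j] is agent i's belief exponents about agent j
  pop$mu <- matrix(0, n, n)
  pop$lam <- matrix(0, n, n)
  # theory of mind: tom_mu[a, b, c] is a's estimate of b's belief about c
  pop$tom_mu <- array(0, c(n, n, n))
  pop$tom_lam <- array(0, c(n, n, n))
  # acquaintance ledgers: messages heard about j / conversations with j
  pop$rm <- matrix(0, n, n)
  pop$rc <- matrix(0, n, n)
  # friendship evidence: pos[a, b] = comparatively positive statements
  # a heard b make about a
  pop$pos <- matrix(0, n, n)
  pop$neg <- matrix(0, n, n)
  # running mean of statement means heard about oneself; initialized at the
  # neutral 0.5 treated as one pseudo-observation
  pop$stmt_mean <- rep(0.5, n)
  pop$stmt_count <- rep(1, n)
  # last message heard per (receiver, speaker, topic), NA until first heard
  pop$last_mu <- array(NA_real_, c(n, n, n))
  pop$last_lam <- array(NA_real_, c(n, n, n))
  # adaptive surprise scales (the perceived social climate), in nats
  pop$kap_h <- rep(constants$initial_scale, n)
  pop$kap_nh <- rep(constants$initial_scale, n)
  pop$kap_lie <- rep(constants$initial_scale, n)
  # engine fast path (in-place C++ reception); the plain-R pipeline is kept
  # as the reference implementation and can be selected for cross-checks
  pop$use_cpp <- TRUE
  # ground-truth message counters (instrumentation, never read by agents)
  pop$n_honest <- 0L
  pop$n_lies <- 0L
  pop$n_blush <- 0L
  class(pop) <- "rg_population"
  pop
}

#' @export
print.rg_population <- function(x, ...) {
  cat(sprintf("<rg_population: %d agents, compression = %s>\n",
              x$n, x$compression))
  invisible(x)
}

#' Friendship of one agent towards another
#'
#' Laplace-smoothed rate of comparatively positive statements `b` made about
#' `a`: `f_ab = (pi + 1) / (pi + nu + 2)`, equal to 1/2 with no data.
#'
#' @param pop An `rg_population`.
#' @param a Owner agent index.
#' @param b Other agent index (vectorized).
#' @return Friendship value(s) in `(0, 1)`.
#' @export
friendship <- function(pop, a, b) {
  p <- pop$pos[a, b]; v <- pop$neg[a, b]
  (p + 1) / (p + v + 2)
}

#' Acquaintance of one agent with another
#'
#' `r_ab = r_m + Q * r_c`: messages `a` heard about `b` plus `Q`-weighted
#' conversations with `b`. The diagonal entry `r_aa` is the
#' self-acquaintance: messages heard about oneself plus `Q`-weighted
#' conversations in which oneself was the topic.
#'
#' @param pop An `rg_population`.
#' @param a Owner agent index.
#' @param b Other agent index (vectorized).
#' @return Nonnegative acquaintance value(s).
#' @export
acquaintance <- function(pop, a, b) {
  pop$rm[a, b] + pop$const$Q * pop$rc[a, b]
}

#' Tabular snapshot of a population's belief and ledger state
#'
#' One row per ordered (owner, subject) pair, suitable for checkpointing and
#' post-hoc metric computation.
#'
#' @param pop An `rg_population`.
#' @return A data.frame with columns `owner`, `subject`, `mu`, `lam`,
#'   `messages_heard`, `conversations`, `positive`, `negative`.
#' @export
population_snapshot <- function(pop) {
  n <- pop$n
  owner <- rep(seq_len(n), times = n)
  subject <- rep(seq_len(n), each = n)
  data.frame(owner = owner, subject = subject,
             mu = as.vector(pop$mu), lam = as.vector(pop$lam),
             messages_heard = as.vector(pop$rm),
             conversations = as.vector(pop$rc),
             positive = as.vector(pop$pos),
             negative = as.vector(pop$neg))
}

#' Write a population snapshot to CSV
#'
#' @param pop An `rg_population`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_snapshot <- function(pop, path) {
  write.csv(population_snapshot(pop), path, row.names = FALSE)
  invisible(path)
}
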