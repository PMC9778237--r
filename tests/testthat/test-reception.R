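msg_of <- function(speaker, topic, mu, lam, blush = FALSE, honest = TRUE) {
  list(speaker = speaker, topic = topic, recipients = integer(0),
       mu = mu, lam = lam, honest = honest, blush = blush)
}

test_that("credibility reduces to the speaker's reputation when the likelihood ratio is 1", {
  pop <- init_population(3, seed = 1)
  pop$mu[2, 1] <- 3; pop$lam[2, 1] <- 0   # mean 0.8
  # equal surprise scales: R(s) = 1 for every surprise
  as_ <- assess_credibility(pop, 2, msg_of(1, 3, 4, 4))
  expect_equal(as_$credibility, 0.8)
  expect_equal(as_$likelihood_ratio, 1)
  expect_equal(as_$speaker_reputation, 0.8)
  expect_identical(as_$cue, "none")
})

test_that("credibility combines reputation prior and surprise likelihood ratio", {
  pop <- init_population(3, seed = 1)
  pop$mu[2, 1] <- 3; pop$lam[2, 1] <- 0   # prior 0.8
  pop$kap_h[2] <- 0.5; pop$kap_nh[2] <- 2  # R(0) = 4
  # payload equal to the prior belief about the topic: zero surprise
  as_ <- assess_credibility(pop, 2, msg_of(1, 3, 0, 0))
  expect_equal(as_$surprise_observed, 0)
  expect_equal(as_$likelihood_ratio, 4)
  expect_equal(as_$credibility, 1 / (1 + 0.25 / 4))
  # monotone decreasing in surprise when honest messages are the calmer ones
  ys <- vapply(c(0.5, 1, 2, 4, 8), function(s_target) {
    pop$mu[2, 3] <- 0; pop$lam[2, 3] <- 0
    d <- lie_delta(0, 0, s_target)
    assess_credibility(pop, 2, msg_of(1, 3, d, 0))$credibility
  }, numeric(1))
  expect_true(all(diff(ys) < 0))
})

test_that("blush and confession cues override the inference", {
  pop <- init_population(3, seed = 1)
  pop$mu[2, 1] <- 30; pop$lam[2, 1] <- 0  # excellent reputation
  as_ <- assess_credibility(pop, 2, msg_of(1, 3, 1, 0, blush = TRUE))
  expect_identical(as_$cue, "blush")
  expect_identical(as_$credibility, 0)
  # confession: self-message strictly more negative than the receiver's view
  pop$mu[2, 1] <- 1; pop$lam[2, 1] <- 1   # view of speaker: 0.5
  as_ <- assess_credibility(pop, 2, msg_of(1, 1, 0, 5)) # mean 1/7 < 1/2
  expect_identical(as_$cue, "confession")
  expect_identical(as_$credibility, 1)
  # equality is not a confession
  as_ <- assess_credibility(pop, 2, msg_of(1, 1, 1, 1)) # mean exactly 1/2
  expect_identical(as_$cue, "none")
  # a blushing self-critical message is still a certain lie
  as_ <- assess_credibility(pop, 2, msg_of(1, 1, 0, 5, blush = TRUE))
  expect_identical(as_$cue, "blush")
  expect_identical(as_$credibility, 0)
})

test_that("credibility stays clipped inside (0, 1) without cues", {
  pop <- init_population(3, seed = 1)
  pop$mu[2, 1] <- 0; pop$lam[2, 1] <- 1000  # abysmal reputation
  as_ <- assess_credibility(pop, 2, msg_of(1, 3, 0, 0))
  expect_gte(as_$credibility, 1e-6)
  pop$mu[2, 1] <- 1000; pop$lam[2, 1] <- 0
  as_ <- assess_credibility(pop, 2, msg_of(1, 3, 0, 0))
  expect_lte(as_$credibility, 1 - 1e-6)
})

test_that("the speaker update adds a credibility-weighted statement count", {
  pop <- init_population(3, seed = 1, compression = "moment_matching")
  pop$mu[2, 1] <- 2; pop$lam[2, 1] <- 3
  expect_identical(update_on_speaker(pop, 2, 1, 1), c(3, 3))
  pop$mu[2, 1] <- 2; pop$lam[2, 1] <- 3
  expect_identical(update_on_speaker(pop, 2, 1, 0), c(2, 4))
  # uncertain case keeps the mean centered but sharpens the state
  pop$mu[2, 1] <- 0; pop$lam[2, 1] <- 0
  st <- update_on_speaker(pop, 2, 1, 0.5)
  expect_equal(beta_mean(st[1], st[2]), 0.5)
  expect_lt(beta_variance(st[1], st[2]), 1 / 12)
})

test_that("theory-of-mind updates blend toward the payload", {
  pop <- init_population(3, seed = 1)
  expect_identical(update_tom(pop, 2, 1, 3, 1, c(4, 2)), c(4, 2))
  pop$tom_mu[2, 1, 3] <- 0; pop$tom_lam[2, 1, 3] <- 0
  expect_identical(update_tom(pop, 2, 1, 3, 0.5, c(4, 2)), c(2, 1))
  st0 <- c(pop$tom_mu[2, 1, 1], pop$tom_lam[2, 1, 1])
  expect_identical(update_tom(pop, 2, 1, 1, 0, c(9, 9)), st0)
})

test_that("novelty filters repeated information", {
  pop <- init_population(3, seed = 1)
  # first message carries everything
  expect_equal(novelty(pop, 2, 1, 3, c(4, 1)), c(4, 1))
  # the same opinion again carries nothing
  expect_equal(novelty(pop, 2, 1, 3, c(4, 1)), c(0, 0))
  # componentwise clipped difference
  expect_equal(novelty(pop, 2, 1, 3, c(6, 0)), c(2, 0))
  # a single statement is at most novelty_cap observations' worth
  inc <- novelty(pop, 2, 1, 2, c(30, 10))
  expect_equal(sum(inc), pop$const$novelty_cap)
  expect_equal(inc[1] / inc[2], 3)
})

test_that("the topic update accepts the novel part with the credibility weight", {
  pop <- init_population(3, seed = 1)
  pop$mu[2, 3] <- 1; pop$lam[2, 3] <- 1
  expect_identical(update_on_topic(pop, 2, 3, 0, c(2, 0)), c(1, 1))
  expect_identical(update_on_topic(pop, 2, 3, 1, c(2, 0)), c(3, 1))
  # uncertain case matches the brute-force KL oracle
  pop$mu[2, 3] <- 0; pop$lam[2, 3] <- 0
  st <- update_on_topic(pop, 2, 3, 0.5, c(2, 0))
  oracle <- oracle_kl_compress(mixture_belief(0.5, c(2, 0), c(0, 0)))
  expect_equal(st, oracle, tolerance = 0.05, ignore_attr = TRUE)
})

test_that("realized surprise is the log-penalty of the assigned probability", {
  expect_identical(record_surprise(1, TRUE), 0)
  expect_equal(record_surprise(0.5, TRUE), log(2))
  expect_equal(record_surprise(0.5, FALSE), log(2))
  expect_equal(record_surprise(0.9, FALSE), -log(0.1))
})

test_that("scales adapt as credibility-weighted moving averages with bounds", {
  pop <- init_population(3, seed = 1)
  as_ <- list(credibility = 1, surprise_observed = 3)
  adapt_scales_and_ledgers(pop, 2, msg_of(1, 3, 0, 0), as_)
  expect_equal(pop$kap_h[2], 0.9 * 1 + 0.1 * 3)  # 1.2
  expect_equal(pop$kap_nh[2], 1)                 # no dishonest evidence
  expect_equal(pop$kap_lie[2], pop$kap_h[2])
  # zero-surprise judged-honest messages drive the honest scale to the floor
  for (i in 1:500)
    adapt_scales_and_ledgers(pop, 2, msg_of(1, 3, 0, 0),
                             list(credibility = 1, surprise_observed = 0))
  expect_equal(pop$kap_h[2], pop$const$scale_floor)
  # cap
  adapt_scales_and_ledgers(pop, 2, msg_of(1, 3, 0, 0),
                           list(credibility = 1, surprise_observed = 1e9))
  expect_equal(pop$kap_h[2], pop$const$scale_cap)
})

test_that("ledgers are monotone and classify self-statements against the running mean", {
  pop <- init_population(3, seed = 1)
  as_ <- list(credibility = 0.5, surprise_observed = 1)
  # message about the receiver with mean above the neutral 0.5: positive
  adapt_scales_and_ledgers(pop, 2, msg_of(1, 2, 4, 0), as_)
  expect_equal(pop$pos[2, 1], 1); expect_equal(pop$neg[2, 1], 0)
  expect_equal(pop$rm[2, 2], 1)
  expect_gt(pop$stmt_mean[2], 0.5)
  # a mediocre message now falls below the raised running mean: negative
  adapt_scales_and_ledgers(pop, 2, msg_of(1, 2, 1, 1), as_)
  expect_equal(pop$neg[2, 1], 1)
  # counters never decrease over a run
  cfg <- run_config(n_agents = 5, n_rounds = 10, seed = 2)
  pop2 <- init_population(5, seed = 2)
  prev <- list(rm = pop2$rm, rc = pop2$rc, pos = pop2$pos, neg = pop2$neg)
  for (r in 1:10) {
    run_round(pop2, r)
    expect_true(all(pop2$rm >= prev$rm) && all(pop2$rc >= prev$rc) &&
                  all(pop2$pos >= prev$pos) && all(pop2$neg >= prev$neg))
    prev <- list(rm = pop2$rm + 0, rc = pop2$rc + 0,
                 pos = pop2$pos + 0, neg = pop2$neg + 0)
  }
})

test_that("the C++ engine path reproduces the reference R pipeline exactly", {
  run_with <- function(use_cpp) {
    pop <- init_population(8, seed = 11)
    pop$use_cpp <- use_cpp
    set.seed(99)
    for (r in 1:12) run_round(pop, r)
    list(mu = pop$mu, lam = pop$lam, tom_mu = pop$tom_mu,
         tom_lam = pop$tom_lam, rm = pop$rm, rc = pop$rc, pos = pop$pos,
         neg = pop$neg, kap_h = pop$kap_h, kap_nh = pop$kap_nh,
         stmt_mean = pop$stmt_mean, last_mu = pop$last_mu)
  }
  fast <- run_with(TRUE)
  ref <- run_with(FALSE)
  for (nm in names(ref)) expect_identical(fast[[nm]], ref[[nm]])
})

test_that("reception runs its updates in the fixed assess-first order", {
  # golden regression: a short recorded run must replay identically
  golden <- read_event_log(test_path("golden", "golden_events.jsonl"))
  res <- run_simulation(run_config(n_agents = 3, n_rounds = 5, seed = 42,
                                   honesty = c(0.1, 0.5, 0.9),
                                   track_acquaintance = FALSE,
                                   record_events = TRUE))
  new <- as.data.frame(res$receptions)
  old <- as.data.frame(golden$receptions)
  expect_equal(nrow(new), nrow(old))
  expect_equal(new$credibility, old$credibility, tolerance = 1e-12)
  expect_identical(new$cue, old$cue)
  expect_equal(new$surprise_observed, old$surprise_observed,
               tolerance = 1e-12)
  newm <- as.data.frame(res$messages); oldm <- as.data.frame(golden$messages)
  expect_equal(newm$mu, oldm$mu, tolerance = 1e-12)
  expect_identical(newm$topic, oldm$topic)
})
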