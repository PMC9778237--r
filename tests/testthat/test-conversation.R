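test_that("partner choice follows the acquaintance/friendship weights", {
  pop <- init_population(3, seed = 1,
                         constants = rg_constants(one_to_many_prob = 0))
  pop$shyness[1] <- 1
  pop$friendship_affinity[1] <- 0
  pop$rm[1, 2] <- 10; pop$rm[1, 3] <- 20
  set.seed(101)
  picks <- vapply(1:10000, function(i) choose_recipients(pop, 1)$recipients,
                  integer(1))
  expect_true(all(picks != 1))
  p3 <- mean(picks == 3)
  expect_lt(abs(p3 - 2 / 3), 3 * sqrt((2 / 9) / 10000))
  # zeroth power: fully extroverted agents choose uniformly
  pop$shyness[1] <- 0
  set.seed(102)
  picks <- vapply(1:10000, function(i) choose_recipients(pop, 1)$recipients,
                  integer(1))
  expect_lt(abs(mean(picks == 3) - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("audience size follows the shyness-weighted distribution", {
  pop <- init_population(6, seed = 2,
                         constants = rg_constants(one_to_many_prob = 1))
  pop$shyness[1] <- 0  # uniform over {2, ..., n-1}
  set.seed(103)
  sizes <- vapply(1:4000, function(i)
    length(choose_recipients(pop, 1)$recipients), integer(1))
  expect_setequal(unique(sizes), 2:5)
  for (k in 2:5)
    expect_lt(abs(mean(sizes == k) - 0.25), 3 * sqrt(0.25 * 0.75 / 4000))
  # recipients never include the initiator, never repeat
  pl <- choose_recipients(pop, 1)
  expect_false(1 %in% pl$recipients)
  expect_equal(anyDuplicated(pl$recipients), 0L)
})

test_that("topic choice weights acquaintance with the topic", {
  pop <- init_population(3, seed = 3,
                         constants = rg_constants(one_to_many_prob = 0))
  pop$shyness[1] <- 1
  pop$rm[1, ] <- c(0, 8, 2)
  set.seed(104)
  topics <- vapply(1:10000, function(i) choose_topic(pop, 1), integer(1))
  expect_false(any(topics == 1))  # zero acquaintance, zero weight
  expect_lt(abs(mean(topics == 2) - 0.8), 3 * sqrt(0.16 / 10000))
  # an agent with only self-acquaintance talks about itself
  pop$rm[1, ] <- c(5, 0, 0)
  expect_true(all(vapply(1:50, function(i) choose_topic(pop, 1),
                         integer(1)) == 1))
  # S = 0: uniform over all topics including self
  pop$shyness[1] <- 0
  set.seed(105)
  topics <- vapply(1:9000, function(i) choose_topic(pop, 1), integer(1))
  for (k in 1:3)
    expect_lt(abs(mean(topics == k) - 1 / 3), 3 * sqrt((2 / 9) / 9000))
})

test_that("honesty decisions are Bernoulli in the intrinsic honesty", {
  pop <- init_population(3, honesty = c(0, 0.3, 1), seed = 4)
  set.seed(106)
  expect_false(any(vapply(1:100, function(i) decide_honest(pop, 1),
                          logical(1))))
  expect_true(all(vapply(1:100, function(i) decide_honest(pop, 3),
                         logical(1))))
  frac <- mean(vapply(1:10000, function(i) decide_honest(pop, 2), logical(1)))
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / 10000))
})

test_that("audience opinions merge through the configured compression", {
  pop <- init_population(4, seed = 5, track_acquaintance = FALSE)
  pop$tom_mu[1, 2, 4] <- 3; pop$tom_lam[1, 2, 4] <- 1
  # single recipient: the theory-of-mind entry itself
  out <- merge_audience_opinion(pop, 1, 2, 4)
  expect_identical(out$opinion, c(3, 1))
  # identical entries collapse to that entry under either compression
  pop$tom_mu[1, 3, 4] <- 3; pop$tom_lam[1, 3, 4] <- 1
  expect_identical(merge_audience_opinion(pop, 1, c(2, 3), 4)$opinion, c(3, 1))
  # distinct entries with equal weights match the brute-force KL oracle
  pop$tom_mu[1, 3, 4] <- 0.5; pop$tom_lam[1, 3, 4] <- 6
  out <- merge_audience_opinion(pop, 1, c(2, 3), 4)
  expect_equal(sum(out$weights), 1)
  oracle <- oracle_kl_compress(mixture_belief(0.5, c(3, 1), c(0.5, 6)))
  expect_equal(out$opinion, oracle, tolerance = 0.05, ignore_attr = TRUE)
})

test_that("honest messages transmit the speaker's belief verbatim", {
  pop <- init_population(3, seed = 6)
  pop$mu[1, 3] <- 2.75; pop$lam[1, 3] <- 0.5
  msg <- construct_message(pop, 1, list(recipients = 2L), 3, honest = TRUE)
  expect_identical(c(msg$mu, msg$lam), c(2.75, 0.5))
  expect_false(msg$blush)
})

test_that("lies shift toward friends, away from enemies, and not at all for strangers", {
  pop <- init_population(3, seed = 7)
  pop$tom_mu[1, 2, 3] <- 2; pop$tom_lam[1, 2, 3] <- 2
  base_mean <- beta_mean(2, 2)
  plan <- list(recipients = 2L)
  # stranger (f exactly 1/2): white lie, payload is the merged base
  set.seed(107)
  msg <- construct_message(pop, 1, plan, 3, honest = FALSE)
  expect_identical(c(msg$mu, msg$lam), c(2, 2))
  # friend: positive shift in mu only
  pop$pos[1, 3] <- 5
  set.seed(108)
  msg <- construct_message(pop, 1, plan, 3, honest = FALSE)
  expect_gt(msg$mu, 2); expect_identical(msg$lam, 2)
  expect_gt(beta_mean(msg$mu, msg$lam), base_mean)
  # enemy: negative shift in lam only
  pop$pos[1, 3] <- 0; pop$neg[1, 3] <- 5
  set.seed(109)
  msg <- construct_message(pop, 1, plan, 3, honest = FALSE)
  expect_identical(msg$mu, 2); expect_gt(msg$lam, 2)
  expect_lt(beta_mean(msg$mu, msg$lam), base_mean)
  # self-topic: always fully positive, even with hostile evidence on file
  pop$neg[1, 1] <- 9
  pop$tom_mu[1, 2, 1] <- 1; pop$tom_lam[1, 2, 1] <- 1
  set.seed(110)
  msg <- construct_message(pop, 1, plan, 1, honest = FALSE)
  expect_gt(msg$mu, 1); expect_identical(msg$lam, 1)
})

test_that("the raw lie size realizes the speaker's climate scale", {
  # the unscaled shift solves KL(shifted || base) = kap_lie
  for (target in c(0.1, 1, 3)) {
    d <- lie_delta(2, 2, target)
    expect_equal(kl_beta(c(2 + d, 2), c(2, 2)), target, tolerance = 1e-6)
  }
  expect_identical(lie_delta(2, 2, 0), 0)
  # unreachable targets cap at the maximum expressible shift
  expect_equal(lie_delta(0, -0.9999, 5), 1e3)
})

test_that("blushing marks a fixed fraction of lies and only lies", {
  cfg <- run_config(n_agents = 10, n_rounds = 60, seed = 8,
                    record_events = TRUE)
  res <- run_simulation(cfg)
  msgs <- as.data.frame(res$messages)
  expect_false(any(msgs$blush[msgs$honest]))
  nl <- sum(!msgs$honest); nb <- sum(msgs$blush)
  expect_lt(abs(nb - 0.1 * nl), 3 * sqrt(nl * 0.1 * 0.9))
})

test_that("the speaker's theory of mind moves convexly toward its message", {
  pop <- init_population(3, seed = 9)
  pop$tom_mu[1, 2, 3] <- 1; pop$tom_lam[1, 2, 3] <- 4
  msg <- list(speaker = 1L, topic = 3L, recipients = 2L,
              mu = 5, lam = 0, honest = TRUE, blush = FALSE)
  speaker_postprocess(pop, msg)
  expect_gte(pop$tom_mu[1, 2, 3], 1); expect_lte(pop$tom_mu[1, 2, 3], 5)
  expect_lte(pop$tom_lam[1, 2, 3], 4); expect_gte(pop$tom_lam[1, 2, 3], 0)
  # other entries untouched
  expect_identical(pop$tom_mu[1, 3, 3], 0)
})
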