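# reputationgame

An agent-based simulator of gossip and reputation dynamics for
computational social psychology. A closed group of agents — each with a
hidden honesty \(x \in [0,1]\), a shyness, and a friendship affinity —
exchanges messages about each other's honesty. Messages may be lies
targeted at what the speaker thinks the audience believes; receivers
judge credibility by approximate Bayesian reasoning and update beliefs
under bounded rationality. The package is for researchers studying
opinion dynamics, trust, and deception in multi-agent systems who want a
fully inspectable, reproducible implementation of this model family.

## The model in brief

Knowledge is stored as beta-form belief states \((\mu, \lambda)\) —
pseudo-counts of honest and dishonest statements, with
\(P(x) \propto x^\mu (1-x)^\lambda\). A receiver judges each message's
credibility by Bayes' rule,

\[
y_J \;=\; \Big[\,1 + \tfrac{1}{R(d)}\big(\bar{x}_{ba}^{-1} - 1\big)\Big]^{-1},
\]

with the speaker's reputation \(\bar{x}_{ba}\) as prior and a
likelihood ratio \(R(d)\) built from telltale cues (blushing: certain
lie; confession: certain truth) and the *surprise* — the KL divergence
of the message from the receiver's prior — measured against adaptively
learned scales (the "social climate"). Posteriors are mixtures of betas;
bounded rationality forces them back into a single beta by one of two
compression algorithms, both implemented and compared:

* **KL-optimal**: minimizes the information loss, equivalently conserves
  \(\langle \ln x \rangle\) and \(\langle \ln(1-x) \rangle\) (damped
  Newton solve of the digamma system);
* **moment matching**: conserves the reputation \(\bar{x}\) and its
  variance (analytic inversion).

Ensemble statistics follow the field's standard definitions: combined
reputation \(\bar{x}_i = (\sum_j \mu_{ji} + 1)/(\sum_j \mu_{ji} +
\sum_j \lambda_{ji} + 2)\), informedness
\(\sum_k (\bar{x}_{ik} - \tfrac12)(x_k - \tfrac12)\), agreement
\(\sum_k (\bar{x}_{ik} - \tfrac12)(\bar{x}_{jk} - \tfrac12)\),
conversation-weighted neighborhood honesty, and per-agent surprise
histograms.

## A worked example

```r
library(reputationgame)

cfg <- run_config(n_agents = 10, n_rounds = 50, seed = 1,
                  record_events = TRUE)
res <- run_simulation(cfg)
res$counters
#> $n_honest
#> [1] 355
#> $n_lies
#> [1] 393
#> $n_blush
#> [1] 35

round(combined_reputation(res$mu, res$lam), 3)
#>  [1] 0.721 0.769 0.203 0.202 0.613 0.814 0.687 0.535 0.476 0.776
round(res$honesty, 3)
#>  [1] 0.000 0.111 0.222 0.333 0.444 0.556 0.667 0.778 0.889 1.000
```

Half the statements were lies (honesties average 0.5), and about one in
ten lies blushed (35 of 393). The reputation vector shows how distorted
a single small group can get: in this run the two strongest liars
(honesty 0 and 0.11) end up *over*rated at 0.72 and 0.77 — they almost
never reveal anything true about themselves, and their self-promoting
lies stick — while the perfectly honest agent is *under*rated at 0.78
and its honest neighbor (0.89) at 0.48, truthful but not believed.
Individual realizations are noisy; the systematic structure emerges at
the ensemble level.

The headline experiment runs the 50-agent ensemble and summarizes it:

```r
out <- fifty_agent_ensemble(n_realizations = 20, seed = 1)
out
#> <rg_fifty_agent: 20 realizations x 50 agents x 300 rounds (kl_optimal)>
#>   identity crossing of reputation curve: 39.9% honesty
#>   mean partners with >= 100 conversations: 25.50
#>   messages: 224164 honest, 226022 lies, 22471 blushes (10.1 lies per blush)
```

The crossing — the honesty below which agents are net overestimated and
above which they are net underestimated — sits well below 50%: gossip
in this model is collectively too critical.

`out$curve` holds the reputation-versus-honesty curve, `out$agents` the
per-agent informedness, agreement, and neighborhood statistics. The
compression comparison experiment is `three_agent_compare()`, and
`inst/cli/repgame.R` exposes `run`, `three-agent`, `fifty-agent`, and
`fixtures` subcommands for shell use.

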