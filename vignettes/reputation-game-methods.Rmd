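---
title: "The reputation game: model, algorithms, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The reputation game: model, algorithms, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reputationgame)
```

## The model

`reputationgame` simulates gossip in a closed group of $n$ agents. Each
agent $a$ has three hidden, immutable traits: an honesty $x_a \in [0,1]$
(the per-statement probability of telling its true belief), a shyness
$S_a$, and a friendship affinity $F_a$. Honesty is simultaneously the
only conversation topic: agents constantly exchange opinions about each
other's honesty and try to work out who can be believed.

All knowledge is carried by *belief states*: pairs of exponents
$(\mu, \lambda)$ parameterizing a beta density
$P(x) \propto x^{\mu}(1-x)^{\lambda}$, interpretable as pseudo-counts of
honest and dishonest statements. An agent's belief book holds one such
state per agent (including itself — its self-esteem, which only messages
from others can move). On top of this sits a rudimentary *theory of
mind*: for every ordered pair (other agent $b$, topic $c$) the agent
stores its estimate of what $b$ currently believes about $c$, which it
needs both to target lies and to anticipate how its statements land.

A simulation proceeds in rounds. Every round each agent initiates one
conversation: with probability one half a one-to-one exchange (which the
partner answers on the same topic), otherwise a one-way broadcast to
$N_b$ recipients, $N_b$ drawn with probability $\propto N_b^{-S_a}$
over $\{2,\dots,n-1\}$. Partners are chosen with probability
$\propto r_{ab}^{S_a} f_{ab}^{F_a}$, where
$r_{ab} = r^m_{ab} + Q\,r^c_{ab}$ is the acquaintance (messages heard
about $b$ plus $Q$-weighted conversations with $b$, $Q = 10$) and
$f_{ab} = (\pi_{ab}+1)/(\pi_{ab}+\nu_{ab}+2)$ the Laplace-smoothed rate
of comparatively positive statements $b$ made about $a$. Topics are
chosen $\propto r_{ac}^{S_a}$, so agents only talk about agents they
have information on.

An honest statement transmits the speaker's belief about the topic
verbatim. A lie starts from the speaker's theory-of-mind estimate of the
audience's opinion (a weighted mixture, compressed to a single beta, if
there are several recipients) so as to stay believable, and shifts it by
$|2f_{ac}-1|\,\Delta$ — upward in $\mu$ for friends ($f_{ac} > 1/2$) and
for the speaker itself (self-promotion, $f$ treated as 1), downward via
$\lambda$ for enemies, not at all for strangers ($f_{ac} = 1/2$, a white
lie). Every tenth lie, on average, is accompanied by a blush.

The receiver judges each message's credibility
$y_J = P(\text{honest} \mid d)$ by Bayes' rule with its current expected
honesty of the speaker $\bar{x}_{ba}$ as prior and a likelihood ratio
$R(d)$ summarizing the evidence. Two cues are decisive: a blush
($y_J = 0$) and a confession — a message about the speaker itself that
is *more negative* than the receiver's current view, which a
self-promoting liar would never send ($y_J = 1$). Otherwise the evidence
is the *surprise* $s$, the KL divergence of the payload from the
receiver's prior belief about the topic, assessed under exponential
surprise models with learned scales $\kappa_h$, $\kappa_{\neg h}$:
$R(s) = \frac{\kappa_h^{-1}e^{-s/\kappa_h}}
{\kappa_{\neg h}^{-1}e^{-s/\kappa_{\neg h}}}$,
so that when lies typically carry larger surprises than honest
statements, a calm message is credible and a wild one is not. The scales
are the agent's perception of the *social climate*; they adapt as
credibility-weighted moving averages of observed surprises, and the
speaker's lie size $\Delta$ is chosen so that the lie's divergence from
the targeted opinion equals its own climate scale — lies are as big as
lies currently seem to be.

Each received message triggers three updates in a fixed order (the
credibility assessment always sees the prior state): the belief about
the speaker becomes the mixture $y_J\,(\mu+1, \lambda) \oplus
(1-y_J)\,(\mu, \lambda+1)$; the theory-of-mind entry for (speaker,
topic) blends toward the payload with weight $y_J$ (a DeGroot-style
update); and the belief about the topic becomes
$y_J\,(\mu+\Delta\mu^+, \lambda+\Delta\lambda^+) \oplus (1-y_J)\,(\mu,
\lambda)$, where $(\Delta\mu^+, \Delta\lambda^+)$ is the *novel* part of
the message — the componentwise clipped difference against the same
speaker's previous statement on the topic, so repetition adds nothing.

## Belief compression

The mixture posteriors above are not beta distributions. Bounded
rationality is modeled by forcing them back into a single beta state
after every update, and the package implements both studied mechanisms:

* **KL-optimal compression** (`compress_kl_optimal`) minimizes
  $D_{KL}(\text{mixture} \,\|\, \text{beta})$, which is equivalent to
  conserving the logarithmic moments $\langle \ln x \rangle$ and
  $\langle \ln(1-x) \rangle$. The mixture's log-moments are the weighted
  sums of the component closed forms (digamma expressions); the inverse
  problem is solved by a damped two-dimensional Newton iteration on the
  digamma system, initialized at the moment-matching solution, with
  residual tolerance $10^{-10}$ and a hard failure (never silent) after
  200 iterations. Because the log-moments weight the edges of $[0,1]$
  heavily, this compression is good at telling honesties near 0 or 1
  apart.
* **Moment-matching compression** (`compress_moment_matching`) conserves
  the mean (the reputation itself) and the variance, by the analytic
  inversion $s = \bar{x}(1-\bar{x})/\sigma^2 - 1$,
  $\mu = \bar{x}s - 1$, $\lambda = (1-\bar{x})s - 1$.

Both compressions are exact on degenerate mixtures. Note that legitimate
mixtures can compress to exponents in $(-1, 0)$ (U-shaped betas), which
is why the exponent domain is $(-1, \infty)$ rather than $[0, \infty)$:
clamping at zero would silently break the conservation contracts.

The KL-optimal method is the package default for the large-group
experiment; the three-agent comparison experiment
(`three_agent_compare`) runs both mechanisms on matched seeds and
contrasts the agents' judgment accuracy via surprise histograms.

## Parameters

| Parameter | Default | Meaning |
|---|---|---|
| `Q` | 10 | conversations vs. heard messages in acquaintance |
| `blush_rate` | 0.1 | fraction of lies that blush |
| `ema_alpha` | 0.1 | adaptation rate of the surprise scales (~10-message memory) |
| `epsilon` | 1e-6 | credibility clipping bound without cues |
| `initial_scale` | 1 nat | starting value of all surprise scales |
| `scale_floor` / `scale_cap` | 1e-3 / 100 nats | bounds of the climate scales |
| `novelty_cap` | 10 | maximum pseudo-counts a single message can contribute |
| `one_to_many_prob` | 0.5 | broadcast vs. dialogue per initiation |

Traits: honesties sit on the even grid $i/(n-1)$ (so the full range is
exhausted deterministically); friendship affinity is uniform on
$[0,1]$; shyness is uniform on $[0,2]$. The shyness range deliberately
reaches into the superlinear regime: partner choice reinforces
acquaintance as $r^S$, and sublinear reinforcement ($S < 1$) provably
never condenses onto favorite partners, whereas the emergent small
conversation groups the model is known for require exactly that
condensation.

## Numerical choices and safeguards

Several safeguards keep a long run inside the regime the model is about,
and are deliberately part of the model (all are exposed in
`rg_constants()` and recorded in run manifests):

* **Bounded confidence.** Stored belief exponents are clamped to
  $[-0.999, 10^6]$ after each update. Iterated KL-optimal compression of
  conflicting sharp messages can otherwise push an exponent arbitrarily
  close to $-1$ — infinite certainty from finitely many messages — and
  destroy the digamma solve.
* **Novelty cap.** One statement carries at most `novelty_cap`
  observations' worth of evidence about the topic (the increment is
  scaled, preserving its honest/dishonest direction). Without it, sharp
  payloads echo through the group and everyone's pseudo-counts inflate
  exponentially — double-counting hearsay as fresh data.
* **Scale adaptation.** Each climate scale moves toward the observed
  surprise at a rate proportional to the evidence for its hypothesis
  ($\alpha y_J$ for the honest scale, $\alpha(1-y_J)$ for the dishonest
  one). A symmetric-rate update would decay the honest scale even when a
  message is judged a certain lie, which collapses the climate and with
  it every credibility in the system.
* **Lie-size cap.** The bisection solving
  $D_{KL}(\text{shifted}\,\|\,\text{base}) = \kappa_{\text{lie}}$ caps
  the shift at $10^3$ pseudo-counts: when the untouched exponent of the
  base is near $-1$ the divergence grows only logarithmically in the
  shift and the target can be unreachable.
* **Credibility clipping** at $\epsilon = 10^{-6}$ keeps recorded
  surprises finite in the absence of cues; cues override the clipping
  exactly ($y_J \in \{0, 1\}$), so a cue that fires against the ground
  truth produces an infinite realized surprise, which the histogram
  collects in an overflow bin.
* **Confession strictness.** Equality of the payload mean with the
  receiver's view is *not* a confession; only strictly more negative
  self-statements are.
* **Degenerate inputs.** Compressing a mixture whose variance is not in
  $(0, \bar{x}(1-\bar{x}))$ is an error (no beta state exists); a
  degenerate mixture returns its surviving component bit-for-bit.

Two further conventions resolve ambiguities of the conversational
protocol: initiators act in fixed index order within a round (maximal
reproducibility; order effects are second-order), and a broadcast counts
as a conversation with each recipient in the acquaintance ledger, while
answers belong to the conversation that prompted them. Answers draw
their own honesty and may themselves blush or confess.

## The engine and reproducibility

The reference implementation of every operation is plain R
(`assess_credibility`, `update_on_speaker`, `update_tom`, `novelty`,
`update_on_topic`, `adapt_scales_and_ledgers`, `speaker_postprocess`);
the engine routes the per-message hot path through an equivalent C++
implementation that mutates the population state in place. A regression
test drives both paths through identical rounds and requires bit-level
equality, so the C++ path cannot drift from the documented R semantics.

All randomness flows through R's RNG. A run is a pure function of its
seed: realization $k$ of an ensemble uses the child seed
$(1009\,\text{seed} + 7919\,k) \bmod 2147483629 + 1$, so any single
realization can be reproduced in isolation. Event logs (JSON lines),
snapshots (CSV), and manifests (JSON, including every behavioral
constant and child seed) make a run fully re-creatable; instrumentation
(realized surprises, which read the ground-truth honesty of a message)
is write-only and never feeds back into agent state, which a test
verifies by comparing final states with instrumentation on and off.

## What the experiments show — and what they cannot

`fifty_agent_ensemble()` runs the large-group study at a reduced default
of 20 realizations (50 agents, 300 rounds; the full-scale study uses
100 realizations) and computes: the ensemble-averaged reputation-versus-
honesty curve with its identity crossing — the boundary between net
overestimated and net underestimated agents, which lands well below 50%
honesty (agents are collectively too critical); per-agent informedness
(centered alignment of belief means with true honesties); pairwise
agreement (centered alignment of two agents' belief vectors); the
conversation-weighted neighborhood honesty and within-neighborhood
reputation; and the emergent group size (partners with at least 100
conversations). Problem sizes in the test suite are chosen so a desk
machine completes the whole suite in minutes; 20 realizations put the
crossing estimate within a few percentage points of its ensemble mean.

These are statements about the model, not about people. The generator
emulates the study conditions — evenly spaced honesties, uniform trait
draws, a closed group, a single gossip topic per message — and none of
the features that make real communication data messy: entering/leaving
participants, multiple simultaneous topics, channel noise, or any
strategic behavior beyond the fixed lying heuristic. Passing tests show
the mechanisms are implemented and interact as designed, not that human
groups behave this way.

Known limitations worth naming: the mean number of strong partners is
sensitive to the unstated trait distributions (with the documented
choices it comes out well above the handful reported for the original
large-group study, though the bound "at least 3" holds robustly); the
all-honest corner case (every honesty exactly 1) is provably
information-free under this credibility rule — no blushes, no
confessions, hence $R \equiv 1$, $y_J = \bar{x}$, and beliefs frozen at
mean $1/2$ — so convergence of beliefs toward 1 in that limit should not
be expected of this design; and with only two compression families
implemented, conclusions about "compression" generalize only as far as
beta-conjugate belief stores.
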