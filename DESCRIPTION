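Package: reputationgame
Title: Agent-Based Gossip and Reputation Dynamics with Bounded-Rational
    Bayesian Agents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates gossip dynamics in groups of agents that exchange
    (possibly deceptive) messages about each other's honesty. Each agent
    stores beta-distributed beliefs about every agent's honesty, judges
    the credibility of incoming messages by approximate Bayesian
    reasoning with a theory of mind, and compresses mixture posteriors
    back into a single beta distribution under bounded rationality.
    Implements two belief-compression algorithms (Kullback-Leibler
    optimal, conserving log-moments, and moment matching, conserving
    mean and variance), the full conversation and reception mechanics
    (partner and topic choice, targeted lies, blushing and confession
    cues, adaptive surprise scales), and ensemble summary statistics
    (reputation, informedness, agreement, neighborhood structure,
    surprise histograms).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
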