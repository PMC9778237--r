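# Reproduction recipes as executable experiments: the three-agent
# compression comparison, the fifty-agent ensemble, and fixture generation.

#' Three-agent compression comparison
#'
#' Runs matched ensembles of the small-group setup (three agents, default
#' honesties 0.1 / 0.5 / 0.9 for the least, intermediately, and most honest
#' agent) under both belief compressions on identical child seeds. In this
#' setup agents do not track acquaintances: partner and topic choice are
#' uniform. The two arms differ only in the compression function. Reported
#' per arm: per-agent surprise histograms (how accurately the agents judge
#' credibility) and combined-reputation trajectories.
#'
#' @param n_realizations Realizations per arm.
#' @param n_rounds Rounds per realization.
#' @param seed Master seed (child seeds matched across arms).
#' @param honesty Honesty vector for the three agents.
#' @param constants See [rg_constants()].
#' @return A list of class `rg_three_agent`: per-arm `surprise` histograms,
#'   `reputation_traj` (mean over realizations, rounds x agents), the
#'   pooled receptions, and the configs.
#' @export
three_agent_compare <- function(n_realizations = 20, n_rounds = 300,
                                seed = 1L, honesty = c(0.1, 0.5, 0.9),
                                constants = rg_constants()) {
  arms <- c("kl_optimal", "moment_matching")
  out <- list(honesty = honesty, configs = list())
  for (arm in arms) {
    cfg <- run_config(n_agents = length(honesty), n_rounds = n_rounds,
                      n_realizations = n_realizations, compression = arm,
                      seed = seed, honesty = honesty,
                      track_acquaintance = FALSE, record_events = TRUE,
                      record_reputation = TRUE, constants = constants)
    ens <- run_realizations(cfg)
    rcps <- lapply(ens$results, `[[`, "receptions")
    traj <- Reduce(`+`, lapply(ens$results, `[[`, "reputation_traj")) /
      n_realizations
    out$configs[[arm]] <- cfg
    out[[arm]] <- list(surprise = surprise_histogram(rcps),
                       reputation_traj = traj,
                       receptions = data.table::rbindlist(rcps))
  }
  class(out) <- "rg_three_agent"
  out
}

#' Fifty-agent ensemble experiment
#'
#' The full group-dynamics pipeline: `n_realizations` realizations of
#' `n_agents` agents with honesties on the even grid `i/(n-1)`, run for
#' `n_rounds` rounds with KL-optimal compression, then summarized into the
#' ensemble statistics: the reputation-versus-honesty curve and its
#' identity crossing (the over/underestimation boundary), per-agent
#' informedness against honesty, neighborhood honesty and neighborhood
#' reputation (over/under-estimation), mean pairwise agreement per agent,
#' and the emergent group size (partners with at least 100 conversations).
#'
#' @param n_realizations Number of realizations (20 gives a desk-scale run;
#'   100 matches the full study).
#' @param n_agents Number of agents.
#' @param n_rounds Rounds per realization.
#' @param seed Master seed.
#' @param compression Belief compression (KL-optimal by default, the
#'   better-performing method in the three-agent comparison).
#' @param partner_threshold Conversation count defining a strong partner.
#' @param constants See [rg_constants()].
#' @return A list of class `rg_fifty_agent` with `curve`, `crossing`
#'   (fraction), `agents` (per agent x realization: honesty, informedness,
#'   neighborhood stats, mean agreement, strong-partner count),
#'   `mean_strong_partners`, `counters` (summed message counts), and the
#'   `ensemble` itself.
#' @export
fifty_agent_ensemble <- function(n_realizations = 20, n_agents = 50,
                                 n_rounds = 300, seed = 1L,
                                 compression = "kl_optimal",
                                 partner_threshold = 100,
                                 constants = rg_constants()) {
  cfg <- run_config(n_agents = n_agents, n_rounds = n_rounds,
                    n_realizations = n_realizations,
                    compression = compression, seed = seed,
                    constants = constants)
  ens <- run_realizations(cfg)
  curve <- reputation_curve(ens)
  per <- vector("list", n_realizations)
  for (k in seq_len(n_realizations)) {
    res <- ens$results[[k]]
    bm <- belief_means(res)
    inf <- informedness(bm, res$honesty)
    agr <- agreement(bm)
    diag(agr) <- NA
    nb <- neighborhood_stats(res)
    per[[k]] <- data.frame(realization = k, agent = seq_len(n_agents),
                           honesty = res$honesty, informedness = inf,
                           mean_agreement = rowMeans(agr, na.rm = TRUE),
                           neighborhood_honesty = nb$neighborhood_honesty,
                           neighborhood_reputation = nb$neighborhood_reputation,
                           over_under = nb$over_under,
                           strong_partners = strong_partners(res,
                                                             partner_threshold))
  }
  agents <- do.call(rbind, per)
  counters <- Reduce(function(x, y) Map(`+`, x, y),
                     lapply(ens$results, `[[`, "counters"))
  structure(list(curve = curve, crossing = identity_crossing(curve),
                 agents = agents,
                 mean_strong_partners = mean(agents$strong_partners),
                 counters = counters, ensemble = ens, config = cfg),
            class = "rg_fifty_agent")
}

#' @export
print.rg_fifty_agent <- function(x, ...) {
  cat(sprintf(paste0(
    "<rg_fifty_agent: %d realizations x %d agents x %d rounds (%s)>\n",
    "  identity crossing of reputation curve: %.1f%% honesty\n",
    "  mean partners with >= %d conversations: %.2f\n",
    "  messages: %d honest, %d lies, %d blushes (%.1f lies per blush)\n"),
    x$config$n_realizations, x$config$n_agents, x$config$n_rounds,
    x$config$compression, 100 * x$crossing, 100,
    x$mean_strong_partners, x$counters$n_honest, x$counters$n_lies,
    x$counters$n_blush, x$counters$n_lies / max(1L, x$counters$n_blush)))
  invisible(x)
}

#' Generate tiny deterministic fixtures
#'
#' Writes a small recorded run (3 agents, 5 rounds) as a JSON-lines event
#' log and a CSV final-state snapshot, for use as golden files in
#' regression tests. Regeneration with the same seed is byte-identical.
#'
#' @param seed Integer seed.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
make_fixtures <- function(seed = 42L, dir = tempdir()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cfg <- run_config(n_agents = 3, n_rounds = 5, seed = seed,
                    honesty = c(0.1, 0.5, 0.9), track_acquaintance = FALSE,
                    record_events = TRUE)
  res <- run_simulation(cfg)
  log_path <- file.path(dir, "fixture_events.jsonl")
  snap_path <- file.path(dir, "fixture_snapshot.csv")
  write_event_log(res, log_path)
  write_snapshot(res$population, snap_path)
  invisible(c(events = log_path, snapshot = snap_path))
}
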