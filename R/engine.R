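# Simulation driver: rounds, conversations with answers, RNG discipline,
# realizations, and artifact output.

#' Run configuration
#'
#' Bundles every knob of a simulation run. All behavioral constants are
#' carried in `constants` and serialized into the run manifest.
#'
#' @param n_agents Number of agents.
#' @param n_rounds Conversation rounds; each round every agent initiates
#'   one conversation.
#' @param n_realizations Independent realizations (fresh traits and RNG).
#' @param compression `"kl_optimal"` or `"moment_matching"`.
#' @param seed Master integer seed; realization k derives a child seed.
#' @param honesty `NULL` for the even grid `i/(n-1)`, or an explicit vector.
#' @param track_acquaintance See [init_population()].
#' @param record_events Keep the per-message / per-reception event log.
#' @param record_reputation Record the combined-reputation trajectory
#'   (per round, per agent).
#' @param constants See [rg_constants()].
#' @return A list of class `rg_config`.
#' @export
run_config <- function(n_agents = 50, n_rounds = 300, n_realizations = 1,
                       compression = c("kl_optimal", "moment_matching"),
                       seed = 1L, honesty = NULL, track_acquaintance = TRUE,
                       record_events = FALSE, record_reputation = FALSE,
                       constants = rg_constants()) {
  compression <- match.arg(compression)
  stopifnot(n_agents >= 2, n_rounds >= 1, n_realizations >= 1)
  structure(list(n_agents = as.integer(n_agents),
                 n_rounds = as.integer(n_rounds),
                 n_realizations = as.integer(n_realizations),
                 compression = compression, seed = as.integer(seed),
                 honesty = honesty,
                 track_acquaintance = isTRUE(track_acquaintance),
                 record_events = isTRUE(record_events),
                 record_reputation = isTRUE(record_reputation),
                 constants = constants),
            class = "rg_config")
}

# Child seed for realization k: deterministic, splittable, below 2^31.
.child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + 7919 * as.numeric(k)) %% 2147483629 + 1)
}

# append a record to a growing log: records live as numbered bindings in a
# hash environment (O(1) append, no list copying)
.log_add <- function(e, nm, rec) {
  cn <- paste0(nm, "_n")
  i <- e[[cn]] + 1L
  e[[cn]] <- i
  assign(paste0(nm, i), rec, envir = e)
  invisible(NULL)
}

.log_collect <- function(e, nm) {
  n <- e[[paste0(nm, "_n")]]
  if (n == 0L) return(data.table::data.table())
  data.table::rbindlist(mget(paste0(nm, seq_len(n)), envir = e))
}

#' Run one conversation round
#'
#' Iterates initiators in fixed index order. Each initiator plans a
#' conversation (recipients, topic), draws honesty, constructs the message,
#' and every recipient processes it. A one-to-one conversation is answered
#' by the recipient on the same topic with a fresh honesty draw; broadcasts
#' are one-way. At the end of each one-to-one exchange the conversation
#' ledgers of both participants are incremented (broadcasts are one-way
#' messages, not conversations: they feed only the messages-heard ledger),
#' and if the topic took part in the conversation its self-acquaintance
#' conversation counter is incremented.
#'
#' @param pop An `rg_population`.
#' @param round Round index (only recorded in the event log).
#' @param log Optional environment collecting event records (internal).
#' @return The population, invisibly (state updated in place).
#' @export
run_round <- function(pop, round = 1L, log = NULL) {
  n <- pop$n
  rec_ev <- !is.null(log)
  for (a in seq_len(n)) {
    plan <- choose_recipients(pop, a)
    topic <- choose_topic(pop, a, plan)
    honest <- decide_honest(pop, a)
    msg <- construct_message(pop, a, plan, topic, honest)
    .count_message(pop, msg)
    if (rec_ev) .log_message(log, round, "initiation", msg)
    for (b in plan$recipients) {
      as_ <- receive_message(pop, b, msg)
      if (rec_ev) .log_reception(log, round, b, msg, as_)
    }
    speaker_postprocess(pop, msg)
    if (plan$mode == "one_to_one") {
      b <- plan$recipients
      h2 <- decide_honest(pop, b)
      ans <- construct_message(pop, b, list(recipients = a), topic, h2)
      .count_message(pop, ans)
      if (rec_ev) .log_message(log, round, "answer", ans)
      as_ <- receive_message(pop, a, ans)
      if (rec_ev) .log_reception(log, round, a, ans, as_)
      speaker_postprocess(pop, ans)
    }
    # every exchange counts as a conversation for both participants; a
    # broadcast counts as one conversation with each recipient
    for (b in plan$recipients) {
      pop$rc[a, b] <- pop$rc[a, b] + 1
      pop$rc[b, a] <- pop$rc[b, a] + 1
      if (topic == a || topic == b)
        pop$rc[topic, topic] <- pop$rc[topic, topic] + 1
    }
  }
  invisible(pop)
}

.count_message <- function(pop, msg) {
  if (msg$honest) {
    pop$n_honest <- pop$n_honest + 1L
  } else {
    pop$n_lies <- pop$n_lies + 1L
    if (msg$blush) pop$n_blush <- pop$n_blush + 1L
  }
  invisible(NULL)
}

.log_message <- function(log, round, type, msg) {
  .log_add(log, "msg", list(
    round = round, type = type, speaker = msg$speaker, topic = msg$topic,
    recipients = paste(msg$recipients, collapse = ","),
    mu = msg$mu, lam = msg$lam, honest = msg$honest, blush = msg$blush))
}

.log_reception <- function(log, round, b, msg, as_) {
  .log_add(log, "rcp", list(
    round = round, receiver = b, speaker = msg$speaker, topic = msg$topic,
    credibility = as_$credibility, cue = as_$cue,
    surprise_observed = as_$surprise_observed,
    realized_surprise = as_$realized_surprise,
    honest = msg$honest))
}

#' Run one simulation realization
#'
#' Initializes a population (traits drawn from the given seed) and runs the
#' configured number of rounds. With the same seed the run is fully
#' deterministic, event log included.
#'
#' @param config An `rg_config` from [run_config()] (its `n_realizations`
#'   is ignored here; see [run_realizations()]).
#' @param seed Seed for this realization; defaults to `config$seed`.
#' @return A list of class `rg_result`: final trait vectors and state
#'   matrices (`mu`, `lam`, `rc`, `rm`), ground-truth message `counters`,
#'   the `seed`, and (if recorded) `messages` and `receptions` data.frames
#'   and a `reputation_traj` matrix (rounds x agents).
#' @export
run_simulation <- function(config, seed = config$seed) {
  pop <- init_population(config$n_agents, honesty = config$honesty,
                         seed = seed, compression = config$compression,
                         track_acquaintance = config$track_acquaintance,
                         constants = config$constants)
  log <- NULL
  if (config$record_events) {
    log <- new.env(parent = emptyenv(), hash = TRUE, size = 4096L)
    log$msg_n <- 0L
    log$rcp_n <- 0L
  }
  traj <- if (config$record_reputation)
    matrix(NA_real_, config$n_rounds, pop$n) else NULL
  for (r in seq_len(config$n_rounds)) {
    run_round(pop, r, log)
    if (!is.null(traj)) traj[r, ] <- combined_reputation(pop$mu, pop$lam)
  }
  # copy the state matrices: the engine mutates them in place
  res <- list(honesty = pop$honesty, shyness = pop$shyness,
              friendship_affinity = pop$friendship_affinity,
              mu = pop$mu + 0, lam = pop$lam + 0,
              rc = pop$rc + 0, rm = pop$rm + 0,
              counters = list(n_honest = pop$n_honest, n_lies = pop$n_lies,
                              n_blush = pop$n_blush),
              compression = config$compression, seed = seed,
              population = pop)
  if (!is.null(log)) {
    res$messages <- .log_collect(log, "msg")
    res$receptions <- .log_collect(log, "rcp")
  }
  if (!is.null(traj)) res$reputation_traj <- traj
  class(res) <- "rg_result"
  res
}

#' Run an ensemble of realizations
#'
#' Realization `k` uses the child seed `(seed * 1009 + 7919 k) mod p + 1`
#' (p = 2147483629), so any single realization can be reproduced alone.
#' Optionally writes per-realization event logs (JSON lines), final-state
#' snapshots (CSV), and a manifest (JSON) to `out_dir`.
#'
#' @param config An `rg_config`.
#' @param out_dir Optional output directory.
#' @param keep_population Keep the full population environment in each
#'   result (default drops it to save memory).
#' @return A list of class `rg_ensemble`: `results` (list of `rg_result`),
#'   `config`, `seeds`.
#' @export
run_realizations <- function(config, out_dir = NULL, keep_population = FALSE) {
  seeds <- vapply(seq_len(config$n_realizations),
                  function(k) .child_seed(config$seed, k), integer(1))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  results <- vector("list", config$n_realizations)
  for (k in seq_len(config$n_realizations)) {
    res <- run_simulation(config, seed = seeds[k])
    if (!is.null(out_dir)) {
      write_snapshot(res$population, file.path(out_dir,
                                               sprintf("snapshot_%03d.csv", k)))
      if (config$record_events)
        write_event_log(res, file.path(out_dir,
                                       sprintf("events_%03d.jsonl", k)))
    }
    if (!keep_population) res$population <- NULL
    results[[k]] <- res
  }
  ens <- structure(list(results = results, config = config, seeds = seeds),
                   class = "rg_ensemble")
  if (!is.null(out_dir)) write_manifest(ens, file.path(out_dir, "manifest.json"))
  ens
}

#' Write the event log of a recorded run as JSON lines
#'
#' Message records and reception (instrumentation) records share one
#' stream, distinguished by a `record` field.
#'
#' @param res An `rg_result` run with `record_events = TRUE`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_event_log <- function(res, path) {
  if (is.null(res$messages))
    stop("run was not recorded; set record_events = TRUE")
  msg <- cbind(record = "message", as.data.frame(res$messages))
  rcp <- cbind(record = "reception", as.data.frame(res$receptions))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (df in list(msg, rcp)) {
    for (i in seq_len(nrow(df)))
      writeLines(jsonlite::toJSON(as.list(df[i, , drop = FALSE]),
                                  auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Read an event log written by [write_event_log()]
#'
#' Validates that every record carries the mandatory fields for its type.
#'
#' @param path JSON-lines file path.
#' @return A list with `messages` and `receptions` data.frames.
#' @export
read_event_log <- function(path) {
  lines <- readLines(path)
  recs <- lapply(lines, jsonlite::fromJSON)
  need_msg <- c("round", "speaker", "topic", "recipients", "mu", "lam",
                "honest", "blush")
  need_rcp <- c("round", "receiver", "speaker", "topic", "credibility",
                "cue", "surprise_observed", "realized_surprise")
  for (r in recs) {
    need <- switch(as.character(r$record), message = need_msg,
                   reception = need_rcp,
                   stop("unknown record type in event log"))
    if (!all(need %in% names(r)))
      stop("malformed event log record: missing ",
           paste(setdiff(need, names(r)), collapse = ", "))
  }
  is_msg <- vapply(recs, function(r) identical(r$record, "message"), logical(1))
  list(messages = data.table::rbindlist(lapply(recs[is_msg], as.list)),
       receptions = data.table::rbindlist(lapply(recs[!is_msg], as.list)))
}

#' Write a run manifest
#'
#' Serializes the full configuration (including every behavioral constant),
#' the package version, and the per-realization child seeds, so that any
#' output can be reproduced exactly.
#'
#' @param ens An `rg_ensemble`.
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_manifest <- function(ens, path) {
  cfg <- ens$config
  man <- list(package_version = as.character(utils::packageVersion("reputationgame")),
              n_agents = cfg$n_agents, n_rounds = cfg$n_rounds,
              n_realizations = cfg$n_realizations,
              compression = cfg$compression, seed = cfg$seed,
              honesty = cfg$honesty,
              track_acquaintance = cfg$track_acquaintance,
              record_events = cfg$record_events,
              record_reputation = cfg$record_reputation,
              constants = cfg$constants, child_seeds = ens$seeds)
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Rebuild a run configuration from a manifest
#'
#' @param path Manifest JSON path.
#' @return An `rg_config` equivalent to the one that produced the manifest.
#' @export
read_manifest <- function(path) {
  man <- jsonlite::fromJSON(path)
  run_config(n_agents = man$n_agents, n_rounds = man$n_rounds,
             n_realizations = man$n_realizations,
             compression = man$compression, seed = man$seed,
             honesty = man$honesty,
             track_acquaintance = man$track_acquaintance,
             record_events = man$record_events,
             record_reputation = man$record_reputation,
             constants = do.call(rg_constants, man$constants))
}
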