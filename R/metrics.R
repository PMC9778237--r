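# Post-hoc ensemble statistics: reputation, informedness, agreement,
# neighborhood honesty/reputation, and surprise histograms.

#' Combined reputation of every agent
#'
#' The reputation of agent `i` is the mean of the product of all other
#' agents' beta beliefs about `i`: with `S_mu = sum_{j != i} mu_ji` and
#' `S_lam = sum_{j != i} lam_ji`, the closed form
#' `(S_mu + 1) / (S_mu + S_lam + 2)` (equivalently a ratio of beta
#' functions). Uninformed contributors (exponents near zero) hardly move
#' the sums, so no explicit exclusion is needed.
#'
#' @param mu,lam Belief matrices (`mu[j, i]` = agent j's exponents about i).
#' @return Numeric vector of reputations in `(0, 1)`, one per agent.
#' @export
combined_reputation <- function(mu, lam) {
  smu <- colSums(mu) - diag(mu)
  sla <- colSums(lam) - diag(lam)
  if (any(!is.finite(smu)) || any(!is.finite(sla)))
    stop("belief exponents must be finite")
  # the product belief exists only for summed exponents > -1; several
  # contributors holding U-shaped (negative-exponent) states can push a sum
  # below that, in which case it is floored at the normalizability boundary
  smu <- pmax(smu, -0.999)
  sla <- pmax(sla, -0.999)
  (smu + 1) / (smu + sla + 2)
}

#' Informedness of each agent
#'
#' Alignment of an agent's belief-mean vector with the true honesties:
#' `sum_k (xbar_ik - 1/2) (x_k - 1/2)`, bilinear in the centered vectors
#' and bounded by `n/4` in magnitude.
#'
#' @param belief_means Matrix of belief means (`[i, k]` = i's expected
#'   honesty of k, including `k = i`).
#' @param honesty True honesty vector.
#' @return Numeric vector, one informedness value per agent.
#' @export
informedness <- function(belief_means, honesty) {
  as.vector((belief_means - 0.5) %*% (honesty - 0.5))
}

#' Pairwise agreement between agents
#'
#' Alignment of two agents' centered belief-mean vectors:
#' `sum_k (xbar_ik - 1/2)(xbar_jk - 1/2)`; symmetric.
#'
#' @param belief_means Matrix of belief means (`[i, k]`).
#' @return Symmetric `n x n` matrix of agreements.
#' @export
agreement <- function(belief_means) {
  cb <- belief_means - 0.5
  cb %*% t(cb)
}

#' Belief means of a result or population
#'
#' @param x An `rg_result` or `rg_population` (anything with `mu`, `lam`
#'   matrices).
#' @return Matrix of `beta_mean` values, `[i, k]` = i's view of k.
#' @export
belief_means <- function(x) beta_mean(x$mu, x$lam)

#' Neighborhood statistics of each agent
#'
#' The neighborhood of agent `i` is the set of agents it had at least one
#' conversation with. Reported per agent: the conversation-count-weighted
#' mean of neighbors' true honesties; the agent's reputation restricted to
#' its neighborhood (same beta-ratio closed form as [combined_reputation()]
#' over neighbors only); and the over/under-estimation, i.e. that
#' neighborhood reputation minus the agent's true honesty. Agents with an
#' empty neighborhood get `NA` in all three columns.
#'
#' @param res An `rg_result` (needs `rc`, `mu`, `lam`, `honesty`).
#' @return A data.frame with columns `agent`, `honesty`,
#'   `neighborhood_honesty`, `neighborhood_reputation`, `over_under`.
#' @export
neighborhood_stats <- function(res) {
  n <- length(res$honesty)
  out <- data.frame(agent = seq_len(n), honesty = res$honesty,
                    neighborhood_honesty = NA_real_,
                    neighborhood_reputation = NA_real_,
                    over_under = NA_real_)
  for (i in seq_len(n)) {
    nb <- setdiff(which(res$rc[i, ] > 0), i)
    if (length(nb) == 0L) next
    w <- res$rc[i, nb]
    out$neighborhood_honesty[i] <- sum(w * res$honesty[nb]) / sum(w)
    smu <- max(sum(res$mu[nb, i]), -0.999)
    sla <- max(sum(res$lam[nb, i]), -0.999)
    rep_i <- (smu + 1) / (smu + sla + 2)
    out$neighborhood_reputation[i] <- rep_i
    out$over_under[i] <- rep_i - res$honesty[i]
  }
  out
}

#' Ensemble-averaged reputation-versus-honesty curve
#'
#' Averages each agent's final combined reputation over realizations per
#' honesty grid point (honesties are deterministic across realizations with
#' the even grid).
#'
#' @param ens An `rg_ensemble` (or plain list of `rg_result`).
#' @return A data.frame with `honesty` and `reputation` (the ensemble mean).
#' @export
reputation_curve <- function(ens) {
  results <- if (inherits(ens, "rg_ensemble")) ens$results else ens
  reps <- vapply(results, function(r) combined_reputation(r$mu, r$lam),
                 numeric(length(results[[1L]]$honesty)))
  data.frame(honesty = results[[1L]]$honesty,
             reputation = rowMeans(reps))
}

#' Identity crossing of a reputation curve
#'
#' Locates the honesty at which the mean reputation curve crosses the
#' identity line, i.e. the boundary between net overestimated (reputation
#' above honesty, at low honesty) and net underestimated agents. The
#' difference curve `reputation - honesty` is first smoothed with a short
#' centered moving average (finite ensembles leave per-grid-point noise
#' that can graze zero and fake extra crossings); its last downward sign
#' change along the grid is taken (the boundary below the permanently
#' underrated region) and refined by linear interpolation between the
#' adjacent grid points.
#'
#' @param curve A data.frame from [reputation_curve()].
#' @param smooth Odd moving-average window for the difference curve
#'   (default 3; 1 disables smoothing).
#' @return The crossing honesty (fraction in `[0, 1]`), or `NA` if the
#'   curve never crosses from above to below.
#' @export
identity_crossing <- function(curve, smooth = 3) {
  x <- curve$honesty
  d <- curve$reputation - x
  if (smooth > 1) {
    half <- (smooth - 1) %/% 2
    d <- vapply(seq_along(d), function(i) {
      mean(d[max(1, i - half):min(length(d), i + half)])
    }, numeric(1))
  }
  m <- length(d)
  idx <- which(d[-m] > 0 & d[-1L] <= 0)
  if (length(idx) == 0L) return(NA_real_)
  i <- max(idx)
  x[i] + d[i] * (x[i + 1L] - x[i]) / (d[i] - d[i + 1L])
}

#' Per-agent count of strong conversation partners
#'
#' Number of distinct partners with whom an agent has had at least
#' `threshold` conversations (the emergent group size).
#'
#' @param res An `rg_result`.
#' @param threshold Minimum number of conversations (default 100).
#' @return Integer vector, one count per agent.
#' @export
strong_partners <- function(res, threshold = 100) {
  rc <- res$rc
  diag(rc) <- 0
  as.integer(rowSums(rc >= threshold))
}

#' Histogram of realized surprises per agent
#'
#' Bins the realized surprises (the `-ln` penalty of each credibility
#' judgment against the true honesty status) of an instrumented event log,
#' per receiving agent. Infinite surprises (a cue that fired on the wrong
#' ground truth) land in the final overflow bin.
#'
#' @param receptions A receptions data.frame (from a recorded run), or a
#'   list of them (pooled, e.g. over realizations).
#' @param breaks Finite bin edges; an overflow bin `[max, Inf]` is added.
#' @return A data.frame with `agent`, `bin_lo`, `bin_hi`, `count`.
#' @export
surprise_histogram <- function(receptions, breaks = seq(0, 10, by = 0.25)) {
  if (!is.data.frame(receptions))
    receptions <- data.table::rbindlist(receptions)
  edges <- c(breaks, Inf)
  agents <- sort(unique(receptions$receiver))
  out <- vector("list", length(agents))
  for (j in seq_along(agents)) {
    s <- receptions$realized_surprise[receptions$receiver == agents[j]]
    idx <- pmin(findInterval(s, edges), length(edges) - 1L)
    cnt <- tabulate(idx, nbins = length(edges) - 1L)
    out[[j]] <- data.frame(agent = agents[j],
                           bin_lo = edges[-length(edges)],
                           bin_hi = edges[-1L], count = cnt)
  }
  do.call(rbind, out)
}
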