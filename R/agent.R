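#' Learning parameters of the cluster-selection agent
#'
#' Four non-negative scalars controlling the weight updates:
#' * `A` (MFavOvrAll): reward for producing the lowest-energy structure seen
#'   anywhere, paid to the batch's overall-best cluster.
#' * `B` (MFavClus): reward for a cluster beating its own best.
#' * `C` (NoNewFavClus): penalty for a selected cluster that fails to beat
#'   its own best.
#' * `D` (Select): over-selection penalty, scaled by the cluster's share of
#'   all selections so far.
#' The tuned optimum for the packaged surrogate models is
#' `A = 79, B = 3, C = 19, D = 68`.
#'
#' @param A,B,C,D non-negative scalars.
#' @return object of class `learning_params`.
#' @export
learning_params <- function(A = 79, B = 3, C = 19, D = 68) {
  if (any(c(A, B, C, D) < 0)) stop("learning parameters must be >= 0")
  structure(list(A = A, B = B, C = C, D = D), class = "learning_params")
}

#' @export
print.learning_params <- function(x, ...) {
  cat(sprintf("<learning_params> A=%g B=%g C=%g D=%g\n", x$A, x$B, x$C, x$D))
  invisible(x)
}

#' Initialise the cluster-selection agent
#'
#' Every cluster starts with the same selection weight (100 by default: large
#' enough that integer-valued learning parameters move selection
#' probabilities smoothly), zero selection counts, and best energies at
#' +Inf.
#'
#' @param n_clusters number of clusters (>= 1).
#' @param initial_weight starting weight per cluster.
#' @param weight_floor lower clamp for weights; the floor is 1 rather than 0
#'   so the negative-probability cutoff also prevents permanent starvation
#'   of a cluster.
#' @return object of class `agent_state`.
#' @export
init_agent <- function(n_clusters, initial_weight = 100, weight_floor = 1) {
  if (n_clusters < 1) stop("n_clusters must be >= 1")
  if (weight_floor <= 0) stop("weight_floor must be > 0")
  if (initial_weight < weight_floor) {
    stop("initial_weight must be >= weight_floor")
  }
  structure(list(weights = rep(initial_weight, n_clusters),
                 selections = integer(n_clusters),
                 total_selections = 0L,
                 best_per_cluster = rep(Inf, n_clusters),
                 best_overall = Inf,
                 weight_floor = weight_floor),
            class = "agent_state")
}

#' @export
print.agent_state <- function(x, ...) {
  cat("<agent_state> ", length(x$weights), " clusters, ",
      x$total_selections, " selections, best overall ",
      if (is.finite(x$best_overall)) sprintf("%.4f eV", x$best_overall)
      else "none", "\n", sep = "")
  cat("  weights:", round(x$weights, 2), "\n")
  invisible(x)
}

#' Cluster selection probabilities
#'
#' Weights normalised to sum one: relative weights 10/20/15/5 give selection
#' probabilities 20%/40%/30%/10%.
#'
#' @param state an `agent_state`.
#' @return numeric probability vector over clusters.
#' @export
selection_probabilities <- function(state) {
  w <- state$weights
  if (length(w) < 1 || any(w < 0)) stop("invalid agent weights")
  total <- sum(w)
  if (total <= 0) stop("degenerate agent state: all weights are zero")
  w / total
}

#' Sample clusters for the next batch
#'
#' Draws `k` cluster ids with replacement according to
#' [selection_probabilities()] and increments the per-cluster and total
#' selection counters. Uses R's global random stream; seed with
#' `set.seed()` for reproducibility.
#'
#' @param state an `agent_state`.
#' @param k number of draws (>= 1).
#' @return list with `ids` (integer vector of length `k`) and the updated
#'   `state`.
#' @export
agent_select <- function(state, k = 1L) {
  if (k < 1) stop("k must be >= 1")
  p <- selection_probabilities(state)
  ids <- sample.int(length(p), size = k, replace = TRUE, prob = p)
  counts <- tabulate(ids, nbins = length(p))
  state$selections <- state$selections + counts
  state$total_selections <- state$total_selections + as.integer(k)
  list(ids = ids, state = state)
}

#' Apply the four-rule weight update after a batch
#'
#' Each result is the minimum energy of one simulated or real EA run from a
#' selected cluster. For each result, with all comparisons made against the
#' best energies recorded *at batch start* (so the update is
#' order-independent within the batch):
#' 1. if its energy is strictly below the overall best seen so far *and* is
#'    the batch's overall minimum, the cluster's weight increases by `A`
#'    (at most one rule-1 reward per batch; exact ties do not fire);
#' 2. if its energy is strictly below the cluster's own best, the weight
#'    increases by `B` (stacking with rule 1);
#' 3. otherwise (rule 2 did not fire) the weight decreases by `C`;
#' 4. always, the weight decreases by
#'    `selections[c] / total_selections * D`, so an over-selected cluster is
#'    penalised harder.
#' Updated weights are clamped at the agent's floor, then the per-cluster
#' and overall bests are committed.
#'
#' @param state an `agent_state` whose counters already reflect the batch's
#'   [agent_select()] call.
#' @param cluster_ids integer vector of selected cluster ids.
#' @param energies numeric vector of run-minimum energies (eV), same length.
#' @param params a [learning_params()].
#' @return the updated `agent_state`. Empty input is a no-op.
#' @export
agent_update <- function(state, cluster_ids, energies, params) {
  stopifnot(inherits(state, "agent_state"), inherits(params, "learning_params"))
  if (length(cluster_ids) == 0) return(state)
  if (length(cluster_ids) != length(energies)) {
    stop("cluster_ids and energies must have the same length")
  }
  if (any(cluster_ids < 1 | cluster_ids > length(state$weights))) {
    stop("invalid cluster id in results")
  }
  best_overall0 <- state$best_overall
  best_cluster0 <- state$best_per_cluster
  batch_min_at <- which.min(energies)  # first index attaining the batch min
  touched <- unique(cluster_ids)
  w <- state$weights
  if (state$total_selections <= 0) stop("selections not recorded for batch")
  for (r in seq_along(cluster_ids)) {
    cl <- cluster_ids[r]
    e <- energies[r]
    rule1 <- r == batch_min_at && e < best_overall0
    rule2 <- e < best_cluster0[cl]
    if (rule1) w[cl] <- w[cl] + params$A
    if (rule2) w[cl] <- w[cl] + params$B else w[cl] <- w[cl] - params$C
    w[cl] <- w[cl] -
      state$selections[cl] / state$total_selections * params$D
  }
  w[touched] <- pmax(w[touched], state$weight_floor)
  state$weights <- w
  for (r in seq_along(cluster_ids)) {
    cl <- cluster_ids[r]
    if (energies[r] < state$best_per_cluster[cl]) {
      state$best_per_cluster[cl] <- energies[r]
    }
  }
  state$best_overall <- min(state$best_overall, min(energies))
  state
}

#' Serialize / restore agent state as JSON
#'
#' @param state an `agent_state`.
#' @param path optional file path; if NULL the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
agent_to_json <- function(state, path = NULL) {
  # +Inf (no energy seen yet) is not representable in JSON; use null
  payload <- list(weights = state$weights,
                  selections = state$selections,
                  total_selections = state$total_selections,
                  best_per_cluster = ifelse(is.finite(state$best_per_cluster),
                                            state$best_per_cluster, NA_real_),
                  best_overall = if (is.finite(state$best_overall))
                    state$best_overall else NA_real_,
                  weight_floor = state$weight_floor)
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname agent_to_json
#' @param json JSON string or path to a JSON file written by
#'   [agent_to_json()].
#' @export
agent_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  st <- init_agent(length(x$weights), weight_floor = x$weight_floor)
  st$weights <- as.numeric(x$weights)
  st$selections <- as.integer(x$selections)
  st$total_selections <- as.integer(x$total_selections)
  bpc <- as.numeric(unlist(x$best_per_cluster))
  bpc[is.na(bpc)] <- Inf
  st$best_per_cluster <- bpc
  bo <- as.numeric(x$best_overall)
  st$best_overall <- if (length(bo) == 0 || is.na(bo)) Inf else bo
  st
}
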