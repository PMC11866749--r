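#' Weighted counts matrix from transition events
#'
#' Accumulates lag-window transition events into a `[destination, origin]`
#' counts matrix. In `"w2"` mode each event contributes its end-of-window
#' adjusted weight `w2`; in `"w2_over_w1"` mode it contributes the ratio
#' `w2 / w1`, which corrects for trajectory duplication only (a lineage
#' cloned into n copies by the window's end contributes 1/n per copy).
#'
#' @param events a data.frame from [slidingWindows()], or a list of such
#'   data.frames from the same lag (e.g. one per run); mixing lags is an
#'   error.
#' @param nStates number of states.
#' @param mode `"w2"` (default) or `"w2_over_w1"`.
#' @return a [CountsMatrix-class].
#' @export
countsObserved <- function(events, nStates, mode = c("w2", "w2_over_w1")) {
  mode <- match.arg(mode)
  if (is.data.frame(events)) events <- list(events)
  lags <- vapply(events, function(e) {
    lg <- attr(e, "lag")
    if (is.null(lg)) stop("events carry no lag attribute")
    as.integer(lg)
  }, integer(1))
  if (length(unique(lags)) != 1L)
    stop("events from mixed lags cannot be combined into one counts matrix")
  tau <- attr(events[[1L]], "tauWE") %||% 1
  ev <- do.call(rbind, events)
  w <- if (mode == "w2") ev$w2 else ev$w2 / ev$w1
  C <- matrix(0, nStates, nStates)
  lin <- ev$start_state * nStates + ev$end_state + 1L
  acc <- rowsum(w, lin)
  C[as.integer(rownames(acc))] <- acc[, 1L]
  lab <- paste0("s", seq_len(nStates) - 1L)
  dimnames(C) <- list(to = lab, from = lab)
  new("CountsMatrix", counts = C, lag = lagSpec(lags[1L], tau), mode = mode)
}

#' One-step transition matrix from a trajectory tree
#'
#' Column-normalizes the observed lag-1 counts. Because per-cycle snapshots
#' are taken before resampling, every one-step transition is on record even
#' when the lineage is merged away immediately afterwards, so this estimate
#' carries no merging bias — which is what qualifies it to complete the
#' squashed lineages in [mbcCounts()].
#'
#' @param tree a [TrajectoryTree-class], or a list of trees (runs pooled).
#' @param mode counting mode, as in [countsObserved()].
#' @param nStates number of states (defaults to tree metadata).
#' @return a [TransitionMatrix-class] at lag 1.
#' @export
oneStepMatrix <- function(tree, mode = c("w2", "w2_over_w1"),
                          nStates = NULL) {
  mode <- match.arg(mode)
  trees <- if (is(tree, "TrajectoryTree")) list(tree) else tree
  if (is.null(nStates))
    nStates <- trees[[1L]]@meta$nStates %||% (max(trees[[1L]]@states) + 1L)
  ev <- lapply(trees, slidingWindows, lag = 1L)
  C <- countsObserved(ev, nStates, mode)
  .normalizeCounts(C@counts, lag = 1L)
}

.normalizeCounts <- function(C, lag) {
  cs <- colSums(C)
  if (any(cs == 0)) {
    bad <- paste0("s", which(cs == 0) - 1L)
    stop("state(s) never observed as a window start (zero column): ",
         paste(bad, collapse = ", "))
  }
  transitionMatrix(sweep(C, 2L, cs, "/"), lag = lag)
}

# T^i by repeated multiplication; column sums renormalized when numerical
# drift exceeds 1e-12
.stochPowers <- function(T1, maxPow) {
  out <- vector("list", maxPow)
  P <- T1
  for (i in seq_len(maxPow)) {
    if (i > 1L) P <- T1 %*% P
    cs <- colSums(P)
    if (max(abs(cs - 1)) > 1e-12) P <- sweep(P, 2L, cs, "/")
    out[[i]] <- P
  }
  out
}

#' Merging-bias-corrected counts matrix
#'
#' Completes the observed counts with the expected outcomes of the lineages
#' merged away inside the lag window:
#' \deqn{C(\tau) = C_{obs}(\tau) + \sum_{i=1}^{n_\tau - 1} T^i M_i,}
#' where `T` is the (bias-free) one-step transition matrix and `M_i` the
#' incomplete-lineage counts with `i` steps remaining. Since the columns of
#' `T` are normalized, each `T^i M_i` term returns exactly the squashed
#' weight to the column of its start state.
#'
#' @param Cobs observed [CountsMatrix-class] at the target lag.
#' @param T1 one-step [TransitionMatrix-class] from [oneStepMatrix()].
#' @param M an [IncompleteEventSet-class] at the same lag and mode.
#' @return a [CountsMatrix-class] with the corrected counts.
#' @export
mbcCounts <- function(Cobs, T1, M) {
  stopifnot(is(Cobs, "CountsMatrix"), is(T1, "TransitionMatrix"),
            is(M, "IncompleteEventSet"))
  n <- nStates(Cobs)
  if (nStates(T1) != n || nrow(M@M[[1L]]) != n)
    stop("dimension mismatch between Cobs, T1 and M")
  nTau <- Cobs@lag@nTau
  if (modelLag(M) != nTau)
    stop(sprintf("M is for lag %d but Cobs is for lag %d",
                 modelLag(M), nTau))
  if (M@mode != Cobs@mode)
    stop("Cobs and M must be built with the same counting mode")
  C <- Cobs@counts
  if (nTau >= 2L) {
    Tp <- .stochPowers(T1@probs, nTau - 1L)
    for (i in seq_len(nTau - 1L)) C <- C + Tp[[i]] %*% M@M[[i]]
  }
  new("CountsMatrix", counts = C, lag = Cobs@lag, mode = Cobs@mode)
}

#' Markov state model from a counts matrix
#'
#' Normalizes each column of the counts by its sum and computes the
#' stationary distribution as the eigenvalue-1 eigenvector
#' ([analyticSteadyState()]). A column with zero counts is an error naming
#' the state.
#'
#' @param C a [CountsMatrix-class].
#' @param kind provenance tag, `"standard"` or `"mbc"`.
#' @param source optional identifier(s) of the source data, kept in the
#'   provenance.
#' @return an [MsmModel-class].
#' @export
msmFromCounts <- function(C, kind = c("standard", "mbc"), source = NULL) {
  kind <- match.arg(kind)
  stopifnot(is(C, "CountsMatrix"))
  Tt <- .normalizeCounts(C@counts, lag = C@lag@nTau)
  pi <- analyticSteadyState(Tt)
  new("MsmModel", transition = Tt, pi = pi,
      provenance = list(kind = kind, mode = C@mode, lag = C@lag@nTau,
                        tauWE = C@lag@tauWE, source = source))
}

#' Root-mean-square log10 error between probability distributions
#'
#' \eqn{\sqrt{\mathrm{mean}_x (\log_{10} p_{est}(x) - \log_{10} p_{ref}(x))^2}},
#' in orders of magnitude. The reference must be strictly positive; zero
#' estimates are floored at `1e-16` with a warning reporting how many states
#' were floored.
#'
#' @param pEst estimated probability vector.
#' @param pRef reference probability vector (strictly positive).
#' @return a single nonnegative number.
#' @export
rmsle <- function(pEst, pRef) {
  stopifnot(length(pEst) == length(pRef))
  if (any(pRef <= 0))
    stop("reference probabilities must be strictly positive")
  nz <- sum(pEst <= 0)
  if (nz > 0) {
    warning(sprintf("%d state(s) with zero estimated probability floored at 1e-16",
                    nz))
    pEst <- pmax(pEst, 1e-16)
  }
  sqrt(mean((log10(pEst) - log10(pRef))^2))
}

# states (0-based) from which the sink set is unreachable, by boolean
# propagation along nonzero transition probabilities
.unreachable <- function(P, sinkIdx) {
  n <- nrow(P)
  reach <- logical(n); reach[sinkIdx] <- TRUE
  repeat {
    # j can reach if any destination k with P[k, j] > 0 can reach
    newReach <- reach | (colSums(P * reach) > 0)
    if (all(newReach == reach)) break
    reach <- newReach
  }
  which(!reach)
}

#' Mean first passage time to a sink set
#'
#' Solves the absorbing-chain linear system for the expected number of lags
#' to first reach any sink state, scaled by the physical time per lag:
#' `h_j = 1 + sum_k T[k, j] h_k` over non-sink `k`. The reciprocal of the
#' steady-state flux equals the MFPT from the post-event state in a
#' unidirectional cycle, which is how the boundary rate of the biased
#' random walk is cross-checked.
#'
#' @param T a [TransitionMatrix-class].
#' @param sinks 0-based sink state(s), nonempty.
#' @param source a single 0-based source state, or a probability vector over
#'   all states to average the MFPT over.
#' @param tauPhys physical time per lag of `T` (default `lag * 1`).
#' @return the MFPT in units of `tauPhys`.
#' @export
mfpt <- function(T, sinks, source = 0L, tauPhys = modelLag(T)) {
  stopifnot(is(T, "TransitionMatrix"), length(sinks) >= 1L)
  P <- T@probs
  n <- nrow(P)
  sinkIdx <- as.integer(sinks) + 1L
  stopifnot(all(sinkIdx >= 1L), all(sinkIdx <= n))
  bad <- .unreachable(P, sinkIdx)
  if (length(bad))
    stop("sink set unreachable from state(s): ",
         paste0("s", bad - 1L, collapse = ", "))
  ns <- setdiff(seq_len(n), sinkIdx)
  h <- numeric(n)
  if (length(ns)) {
    Q <- P[ns, ns, drop = FALSE]
    h[ns] <- solve(diag(length(ns)) - t(Q), rep(1, length(ns)))
  }
  if (length(source) == 1L) {
    si <- as.integer(source) + 1L
    stopifnot(si >= 1L, si <= n)
    h[si] * tauPhys
  } else {
    stopifnot(length(source) == n, abs(sum(source) - 1) < 1e-8)
    sum(source * h) * tauPhys
  }
}

#' Export a transition matrix as a conformation space network
#'
#' Builds a directed graph whose nodes are the model states — annotated
#' with their stationary weight and any user scalars — and whose edges are
#' the off-diagonal transition probabilities exceeding `edgeThreshold`.
#' Self-loops are never emitted.
#'
#' @param T a [TransitionMatrix-class].
#' @param nodeValues optional named list of per-state numeric vectors to
#'   attach as node attributes.
#' @param edgeThreshold minimum transition probability for an edge
#'   (default 0.005).
#' @param path optional file path; when given, the graph is also written as
#'   GraphML.
#' @return an [igraph::igraph] object (invisibly when `path` is given).
#' @export
exportCsn <- function(T, nodeValues = NULL, edgeThreshold = 0.005,
                      path = NULL) {
  stopifnot(is(T, "TransitionMatrix"), edgeThreshold >= 0)
  P <- T@probs
  n <- nrow(P)
  A <- P
  diag(A) <- 0
  A[A <= edgeThreshold] <- 0
  # igraph's adjacency convention is [from, to]; ours is [to, from]
  g <- igraph::graph_from_adjacency_matrix(t(A), mode = "directed",
                                           weighted = TRUE)
  igraph::V(g)$name <- paste0("s", seq_len(n) - 1L)
  pi <- tryCatch(analyticSteadyState(T), error = function(e) rep(NA_real_, n))
  igraph::V(g)$stationary <- as.numeric(pi)
  if (!is.null(nodeValues))
    for (nm in names(nodeValues))
      g <- igraph::set_vertex_attr(g, nm, value = nodeValues[[nm]])
  if (!is.null(path)) {
    igraph::write_graph(g, path, format = "graphml")
    return(invisible(g))
  }
  g
}
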