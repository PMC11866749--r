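.asNTau <- function(lag) {
  if (is(lag, "LagSpec")) lag@nTau else as.integer(lag)
}

# cumulative log clone-division factor: logDc[t, w] is the log of the
# product of cloneFrac along the lineage of walker w from cycle 1 to t.
# Ratios of exp(logDc) between two cycles of one lineage give the
# clone-division factor across that window (merge gains excluded).
.logCloneCum <- function(tree) {
  Tn <- nCycles(tree); N <- nWalkers(tree)
  L <- matrix(0, Tn, N)
  if (Tn > 1) for (t in 2:Tn)
    L[t, ] <- L[t - 1L, tree@parents[t, ]] + log(tree@cloneFrac[t, ])
  L
}

# ancestor matrix: A[t, w] = index at cycle t - lag of the lineage of
# walker w at cycle t; NA where the window would start before cycle 1.
.ancestorMatrix <- function(parents, lag) {
  Tn <- nrow(parents); N <- ncol(parents)
  A <- matrix(rep(seq_len(N), each = Tn), Tn, N)
  if (lag == 0L) return(A)
  tIdx <- matrix(seq_len(Tn), Tn, N)
  for (l in seq_len(lag)) {
    r <- tIdx - l + 1L
    ok <- r >= 2L & !is.na(A)
    Anew <- matrix(NA_integer_, Tn, N)
    Anew[ok] <- parents[(A[ok] - 1L) * Tn + r[ok]]
    A <- Anew
  }
  A
}

#' Extract lag-window transition events from a trajectory tree
#'
#' Slides a window of `lag` cycles over the tree (stride-1 fully overlapping
#' starts by default) and emits one transition event per surviving lineage
#' path: branched lineages yield one event per leaf at the window's end,
#' while lineages terminated by merging inside the window yield no event
#' here (they are collected by [collectIncomplete()]).
#'
#' Event weights come from the adjusted table anchored at each window's
#' start cycle ([adjustedWeightTable()]): `w1` is the recorded weight of the
#' lineage's ancestor at the start, and `w2` is `w1` divided by the clone
#' multiplicity accumulated inside the window — merge gains never inflate
#' `w2`, so `w2 <= w1` always.
#'
#' @param tree a [TrajectoryTree-class].
#' @param lag integer lag in cycles (>= 1) or a [LagSpec-class].
#' @param stride spacing between window starts (default 1).
#' @return data.frame with columns `start_cycle`, `start_state`,
#'   `end_state` (0-based states), `w1`, `w2`.
#' @export
slidingWindows <- function(tree, lag, stride = 1L) {
  nTau <- .asNTau(lag)
  Tn <- nCycles(tree)
  stopifnot(nTau >= 1L, nTau <= Tn - 1L, stride >= 1L)
  A <- .ancestorMatrix(tree@parents, nTau)
  L <- .logCloneCum(tree)
  rows <- seq.int(nTau + 1L, Tn)
  rows <- rows[(rows - nTau - 1L) %% stride == 0L]
  Asub <- A[rows, , drop = FALSE]
  sIdx <- (Asub - 1L) * Tn + (rows - nTau)
  w1 <- tree@weights[sIdx]
  w2 <- w1 * exp(L[rows, , drop = FALSE] - L[sIdx])
  ev <- data.frame(
    start_cycle = rep(rows - nTau, times = nWalkers(tree)),
    start_state = tree@states[sIdx],
    end_state = as.vector(tree@states[rows, , drop = FALSE]),
    w1 = as.vector(w1), w2 = as.vector(w2))
  attr(ev, "lag") <- nTau
  attr(ev, "tauWE") <- tree@tauWE
  ev
}

#' Clone-division-only weight table anchored at a cycle
#'
#' Recomputes lineage weights forward from `fromCycle`, starting from the
#' recorded weights at that cycle: cloning divides a lineage's weight among
#' its clones, but merging transfers *no* weight to the kept walker — the
#' squashed weight simply leaves the table. This isolates where the weight
#' present at `fromCycle` is transported, which is what lag-window counting
#' needs; the weight removed by squashes is exactly what the M_i matrices
#' of [collectIncomplete()] compensate.
#'
#' @param tree a [TrajectoryTree-class].
#' @param fromCycle anchor cycle (1-based, `<= nCycles(tree)`).
#' @return numeric `[cycle, walker]` matrix; rows before `fromCycle` are
#'   `NA`.
#' @export
adjustedWeightTable <- function(tree, fromCycle = 1L) {
  Tn <- nCycles(tree)
  stopifnot(fromCycle >= 1L, fromCycle <= Tn)
  adj <- matrix(NA_real_, Tn, nWalkers(tree))
  adj[fromCycle, ] <- tree@weights[fromCycle, ]
  if (fromCycle < Tn) for (t in (fromCycle + 1L):Tn)
    adj[t, ] <- adj[t - 1L, tree@parents[t, ]] * tree@cloneFrac[t, ]
  adj
}

#' Collect incomplete-lineage matrices M_1 .. M_{nTau-1}
#'
#' For every lag-window start `s` and every lineage squashed at cycle `t`
#' with `s < t < s + nTau`, adds the lineage's anchored adjusted weight
#' (`mode = "w2"`) or adjusted weight ratio (`mode = "w2_over_w1"`) to
#' `M_i[k, j]`, where `i = s + nTau - t` is the number of cycles left in the
#' window, `k` the state at the squash, and `j` the state at the window
#' start. A lineage squashed at the resampling step right after the
#' window's *end* cycle still yields a complete event (its end snapshot
#' exists), so `i` never reaches 0; a lineage squashed right after the
#' window's start is treated as never launched for that window.
#'
#' @param tree a [TrajectoryTree-class].
#' @param lag integer lag (>= 2) or a [LagSpec-class].
#' @param mode `"w2"` or `"w2_over_w1"`; must match the mode used for the
#'   observed counts the correction will be added to.
#' @param nStates number of states (defaults to the tree's metadata).
#' @return an [IncompleteEventSet-class].
#' @export
collectIncomplete <- function(tree, lag, mode = c("w2", "w2_over_w1"),
                              nStates = NULL) {
  mode <- match.arg(mode)
  nTau <- .asNTau(lag)
  Tn <- nCycles(tree)
  stopifnot(nTau >= 2L, nTau <= Tn - 1L)
  if (is.null(nStates))
    nStates <- tree@meta$nStates %||% (max(tree@states) + 1L)
  M <- replicate(nTau - 1L, matrix(0, nStates, nStates), simplify = FALSE)
  sq <- tree@squashes
  if (nrow(sq)) {
    L <- .logCloneCum(tree)
    u <- sq$cycle; w0 <- sq$walker; f <- sq$frac
    kIdx <- tree@states[(w0 - 1L) * Tn + u] + 1L
    logDu <- L[(w0 - 1L) * Tn + u]
    anc <- w0
    for (l in seq_len(nTau - 1L)) {
      alive <- u - l >= 1L
      anc[alive] <- tree@parents[(anc[alive] - 1L) * Tn + (u[alive] - l + 1L)]
      use <- alive & (u - l + nTau <= Tn)
      if (any(use)) {
        sPos <- (anc[use] - 1L) * Tn + (u[use] - l)
        ratio <- exp(logDu[use] - L[sPos]) * f[use]
        wts <- if (mode == "w2") tree@weights[sPos] * ratio else ratio
        jIdx <- tree@states[sPos] + 1L
        lin <- (jIdx - 1L) * nStates + kIdx[use]
        acc <- rowsum(wts, lin)
        i <- nTau - l
        M[[i]][as.integer(rownames(acc))] <-
          M[[i]][as.integer(rownames(acc))] + acc[, 1L]
      }
    }
  }
  lab <- paste0("s", seq_len(nStates) - 1L)
  M <- lapply(M, function(m) { dimnames(m) <- list(to = lab, from = lab); m })
  new("IncompleteEventSet", M = M, lag = lagSpec(nTau, tree@tauWE),
      mode = mode)
}

#' Where do merged-away lineages end up?
#'
#' Diagnostic for merging bias: among lineages that were in `startState`
#' exactly `lag` cycles before being terminated by merging, the normalized
#' (adjusted-weight) distribution of the states where they were squashed.
#' If merging removed lineages at random, this would match column
#' `startState` of the analytic `T^lag`; systematic skew — e.g. excess mass
#' on the downhill side — is the signature of merging bias.
#'
#' @param tree a [TrajectoryTree-class].
#' @param startState 0-based origin state.
#' @param lag number of cycles between leaving `startState` and the squash
#'   (>= 1).
#' @param nStates number of states (defaults to the tree's metadata).
#' @return named probability vector over squash states.
#' @export
mergingBiasHistogram <- function(tree, startState, lag, nStates = NULL) {
  nTau <- .asNTau(lag)
  Tn <- nCycles(tree)
  stopifnot(nTau >= 1L)
  if (is.null(nStates))
    nStates <- tree@meta$nStates %||% (max(tree@states) + 1L)
  sq <- tree@squashes
  h <- numeric(nStates)
  if (nrow(sq)) {
    L <- .logCloneCum(tree)
    u <- sq$cycle; w0 <- sq$walker; f <- sq$frac
    kIdx <- tree@states[(w0 - 1L) * Tn + u] + 1L
    logDu <- L[(w0 - 1L) * Tn + u]
    anc <- w0
    for (l in seq_len(nTau)) {
      alive <- u - l >= 1L
      anc[alive] <- tree@parents[(anc[alive] - 1L) * Tn + (u[alive] - l + 1L)]
    }
    use <- u - nTau >= 1L
    sPos <- (anc[use] - 1L) * Tn + (u[use] - nTau)
    from <- tree@states[sPos]
    sel <- from == startState
    if (any(sel)) {
      wts <- tree@weights[sPos][sel] *
        exp(logDu[use][sel] - L[sPos][sel]) * f[use][sel]
      acc <- rowsum(wts, kIdx[use][sel])
      h[as.integer(rownames(acc))] <- acc[, 1L]
    }
  }
  if (sum(h) == 0)
    stop(sprintf("no merged-away lineages found starting from state %d at lag %d",
                 startState, nTau))
  h <- h / sum(h)
  names(h) <- paste0("s", seq_len(nStates) - 1L)
  h
}
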