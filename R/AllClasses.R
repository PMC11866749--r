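#' @import methods
NULL

.TOL_WEIGHT <- 1e-9

#' One-dimensional biased random walk specification
#'
#' Describes a discrete chain of `nStates` positions in which a walker hops
#' forward with probability `pFwd` and backward with probability `pBwd` at
#' every step. At position 0 the backward move becomes a self-transition;
#' when `warp` is `TRUE`, the forward move out of the last state returns the
#' walker to state 0, so the stationary flux through the boundary is a
#' well-defined rate.
#'
#' @slot nStates integer, number of discrete states (>= 2).
#' @slot pFwd forward hopping probability per step.
#' @slot pBwd backward hopping probability per step; `pFwd + pBwd` must be 1.
#' @slot warp logical, whether the last state's forward move re-enters state 0.
#'
#' @seealso [chainSpec()], [buildBrwMatrix()]
#' @export
setClass("ChainSpec",
  representation(nStates = "integer", pFwd = "numeric", pBwd = "numeric",
                 warp = "logical"),
  prototype(nStates = 16L, pFwd = 0.25, pBwd = 0.75, warp = TRUE))

setValidity("ChainSpec", function(object) {
  msg <- character()
  if (length(object@nStates) != 1L || object@nStates < 2L)
    msg <- c(msg, "nStates must be a single integer >= 2")
  if (object@pFwd < 0 || object@pBwd < 0)
    msg <- c(msg, "hopping probabilities must be nonnegative")
  if (object@pFwd + object@pBwd != 1)
    msg <- c(msg, "pFwd + pBwd must equal 1 exactly")
  if (length(msg)) msg else TRUE
})

#' Column-stochastic transition matrix
#'
#' Probability matrix over a discrete state space with the column-stochastic
#' convention used throughout the package: entry `[k, j]` is the probability
#' of moving from origin state `j` to destination state `k` over `lag`
#' resampling intervals. Columns index the origin state and each column sums
#' to 1. State labels are 0-based (`"s0"`, `"s1"`, ...) and stored in the
#' dimnames.
#'
#' @slot probs numeric matrix, `[k, j] = P(j -> k)`; columns sum to 1.
#' @slot lag integer, lag in units of the resampling interval.
#'
#' @seealso [transitionMatrix()], [buildBrwMatrix()], [analyticSteadyState()]
#' @export
setClass("TransitionMatrix",
  representation(probs = "matrix", lag = "integer"))

setValidity("TransitionMatrix", function(object) {
  p <- object@probs
  msg <- character()
  if (nrow(p) != ncol(p)) msg <- c(msg, "probs must be square")
  if (any(p < -1e-15) || any(p > 1 + 1e-12))
    msg <- c(msg, "entries must lie in [0, 1]")
  cs <- colSums(p)
  if (any(abs(cs - 1) > 1e-10))
    msg <- c(msg, sprintf("columns must sum to 1 (max deviation %.3g)",
                          max(abs(cs - 1))))
  if (length(object@lag) != 1L || object@lag < 1L)
    msg <- c(msg, "lag must be a single integer >= 1")
  if (length(msg)) msg else TRUE
})

#' Markov lag specification
#'
#' A Markov lag expressed both in physical time (`tau`) and in integer
#' multiples of the resampling interval (`nTau = tau / tauWE`).
#'
#' @slot nTau integer, lag in resampling intervals (>= 1).
#' @slot tauWE numeric, physical time per resampling interval.
#' @export
setClass("LagSpec", representation(nTau = "integer", tauWE = "numeric"))

setValidity("LagSpec", function(object) {
  if (length(object@nTau) != 1L || object@nTau < 1L)
    return("nTau must be a single integer >= 1")
  if (object@tauWE <= 0) return("tauWE must be positive")
  TRUE
})

#' Branched record of a weighted-ensemble run
#'
#' Stores, for every cycle, the post-dynamics (pre-resampling) snapshot of
#' all walkers — their states and statistical weights — together with the
#' resampling bookkeeping that maps each cycle onto the next: the parent of
#' every walker, the fraction of the parent's weight a lineage retains under
#' clone-division-only accounting (`cloneFrac`), the lineages terminated by
#' merging (`squashes`), and a human-readable fate tag per walker.
#'
#' The snapshot-then-resample ordering means one-step transitions are always
#' complete: a walker merged away immediately after a step still has its
#' post-step snapshot on record.
#'
#' @slot states integer matrix `[cycle, walker]` of 0-based state labels.
#' @slot weights numeric matrix of post-dynamics weights; each row sums to 1.
#' @slot parents integer matrix; `parents[c, w]` is the walker index at cycle
#'   `c - 1` this lineage descends from (0 at cycle 1).
#' @slot cloneFrac numeric matrix; fraction of the parent's clone-divided
#'   weight carried into cycle `c` (1 unless the parent was cloned).
#' @slot squashes data.frame with columns `cycle` (last snapshot cycle of the
#'   terminated lineage), `walker` (its index at that cycle), `frac` (its
#'   clone-divided fraction at termination), `into` (index of the absorbing
#'   walker at the same cycle).
#' @slot fates character matrix of per-walker resampling outcome tags
#'   (`CONTINUED`, `CLONED(n)`, `SQUASHED(m)`, `KEPT_MERGE(...)`).
#' @slot tauWE numeric, physical time per cycle.
#' @slot meta list of run provenance (seed, resampler mode, chain, params).
#'
#' @seealso [runSimulation()], [slidingWindows()], [collectIncomplete()]
#' @export
setClass("TrajectoryTree",
  representation(states = "matrix", weights = "matrix", parents = "matrix",
                 cloneFrac = "matrix", squashes = "data.frame",
                 fates = "matrix", tauWE = "numeric", meta = "list"))

setValidity("TrajectoryTree", function(object) {
  msg <- character()
  d <- dim(object@states)
  for (sl in c("weights", "parents", "cloneFrac", "fates"))
    if (!identical(dim(slot(object, sl)), d))
      msg <- c(msg, sprintf("dim(%s) must match dim(states)", sl))
  if (length(msg)) return(msg)
  rs <- rowSums(object@weights)
  if (any(abs(rs - 1) > .TOL_WEIGHT))
    msg <- c(msg, sprintf(
      "per-cycle weights must sum to 1 (max deviation %.3g)", max(abs(rs - 1))))
  if (d[1] > 1) {
    p <- object@parents[-1, , drop = FALSE]
    if (any(p < 1L) || any(p > d[2]))
      msg <- c(msg, "parents beyond cycle 1 must index a previous-cycle walker")
  }
  sq <- object@squashes
  need <- c("cycle", "walker", "frac", "into")
  if (!all(need %in% names(sq)))
    msg <- c(msg, "squashes must have columns cycle, walker, frac, into")
  if (object@tauWE <= 0) msg <- c(msg, "tauWE must be positive")
  if (length(msg)) msg else TRUE
})

#' Weighted transition counts at a fixed lag
#'
#' Nonnegative matrix of weighted, lag-`nTau` transition counts with the same
#' column-origin convention as [TransitionMatrix-class]: `counts[k, j]` holds
#' the accumulated weight of observed `j -> k` transitions. `mode` records
#' whether events were counted by their end-of-window weight (`"w2"`) or by
#' the duplication-only ratio (`"w2_over_w1"`).
#'
#' @slot counts numeric matrix of nonnegative weighted counts.
#' @slot lag a [LagSpec-class].
#' @slot mode `"w2"` or `"w2_over_w1"`.
#' @export
setClass("CountsMatrix",
  representation(counts = "matrix", lag = "LagSpec", mode = "character"))

setValidity("CountsMatrix", function(object) {
  msg <- character()
  if (nrow(object@counts) != ncol(object@counts))
    msg <- c(msg, "counts must be square")
  if (any(!is.finite(object@counts)) || any(object@counts < 0))
    msg <- c(msg, "counts must be finite and nonnegative")
  if (!object@mode %in% c("w2", "w2_over_w1"))
    msg <- c(msg, "mode must be 'w2' or 'w2_over_w1'")
  if (length(msg)) msg else TRUE
})

#' Incomplete-lineage count matrices M_i
#'
#' For a lag of `nTau` resampling intervals, `M[[i]][k, j]` accumulates the
#' clone-divided weight (or weight ratio, matching `mode`) of lineages that
#' started a lag window in state `j`, reached state `k`, and were terminated
#' by merging with `i` intervals still remaining in the window
#' (`1 <= i <= nTau - 1`). These are the correction terms completed by powers
#' of the one-step transition matrix in [mbcCounts()].
#'
#' @slot M list of `nTau - 1` square matrices, element `i` for `i` remaining
#'   intervals.
#' @slot lag a [LagSpec-class].
#' @slot mode counting mode, as in [CountsMatrix-class].
#' @export
setClass("IncompleteEventSet",
  representation(M = "list", lag = "LagSpec", mode = "character"))

setValidity("IncompleteEventSet", function(object) {
  if (object@lag@nTau < 2L) return("lag must be >= 2 for incomplete events")
  if (length(object@M) != object@lag@nTau - 1L)
    return("M must hold nTau - 1 matrices")
  for (m in object@M) {
    if (!is.matrix(m) || nrow(m) != ncol(m)) return("each M_i must be square")
    if (any(!is.finite(m)) || any(m < 0))
      return("M_i entries must be finite and nonnegative")
  }
  TRUE
})

#' Estimated Markov state model
#'
#' Bundles a column-stochastic transition matrix estimated at some lag with
#' its stationary distribution and provenance (standard vs merging-bias
#' corrected, counting mode, lag, and source identifiers).
#'
#' @slot transition a [TransitionMatrix-class].
#' @slot pi numeric stationary probability vector (sums to 1).
#' @slot provenance list with at least `kind` (`"standard"` or `"mbc"`),
#'   `mode`, and `lag`.
#' @export
setClass("MsmModel",
  representation(transition = "TransitionMatrix", pi = "numeric",
                 provenance = "list"))

setValidity("MsmModel", function(object) {
  if (length(object@pi) != nrow(object@transition@probs))
    return("pi length must match the transition matrix dimension")
  if (abs(sum(object@pi) - 1) > 1e-8) return("pi must sum to 1")
  if (any(object@pi < -1e-12)) return("pi must be nonnegative")
  TRUE
})

#' REVO resampler parameters
#'
#' Tunables of the variation-optimization resampler. The trajectory variation
#' is \eqn{V = \sum_{i \ne j} (d_{ij}/d_0)^\alpha \phi_i \phi_j} with the
#' novelty \eqn{\phi(w) = \log w - \log(p_{min}/C)}. Merging is restricted by
#' `mergeMode`/`mergeDist` and by the maximum walker weight `pMax`; cloning
#' never produces a walker lighter than `pMin`.
#'
#' @slot d0 characteristic distance making the variation unitless.
#' @slot alpha exponent on the scaled pairwise distance.
#' @slot pMin minimum allowed walker weight.
#' @slot pMax maximum allowed walker weight.
#' @slot C novelty constant.
#' @slot mergeMode `"strict"`, `"lenient"`, or `"none"`.
#' @slot mergeDist maximum pairwise distance eligible for merging.
#' @slot epsilon minimum variation gain required to accept a proposal.
#' @slot maxOps maximum number of coupled clone/merge events executed per
#'   resampling step (0 = unlimited greedy ascent to a local maximum).
#' @seealso [revoParams()], [revoResample()]
#' @export
setClass("RevoParams",
  representation(d0 = "numeric", alpha = "numeric", pMin = "numeric",
                 pMax = "numeric", C = "numeric", mergeMode = "character",
                 mergeDist = "numeric", epsilon = "numeric",
                 maxOps = "integer"))

setValidity("RevoParams", function(object) {
  msg <- character()
  if (object@d0 <= 0) msg <- c(msg, "d0 must be positive")
  if (!(object@pMin > 0 && object@pMin < object@pMax && object@pMax <= 1))
    msg <- c(msg, "need 0 < pMin < pMax <= 1")
  if (object@C <= 0) msg <- c(msg, "C must be positive")
  if (!object@mergeMode %in% c("strict", "lenient", "none"))
    msg <- c(msg, "mergeMode must be 'strict', 'lenient' or 'none'")
  if (object@mergeDist < 0) msg <- c(msg, "mergeDist must be >= 0")
  if (object@epsilon < 0) msg <- c(msg, "epsilon must be >= 0")
  if (length(object@maxOps) != 1L || object@maxOps < 0L)
    msg <- c(msg, "maxOps must be a single integer >= 0")
  if (length(msg)) msg else TRUE
})
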