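#' Construct REVO resampler parameters
#'
#' Defaults follow the biased-random-walk benchmark configuration:
#' characteristic distance `d0 = 0.25`, novelty constant `C = 100`, distance
#' exponent `alpha = 4`, and the REVO reference-implementation weight bounds
#' `pMin = 1e-12`, `pMax = 0.1`. `mergeDist` defaults by mode — `0` for
#' `"strict"` (only identical states merge) and `1` for `"lenient"`
#' (adjacent states may merge), in state units.
#'
#' @param mergeMode `"strict"`, `"lenient"`, or `"none"`.
#' @param d0 characteristic distance.
#' @param alpha exponent on the scaled distance in the variation.
#' @param pMin minimum allowed walker weight.
#' @param pMax maximum allowed walker weight.
#' @param C novelty constant.
#' @param mergeDist maximum inter-walker distance eligible for merging;
#'   `NULL` picks the mode default.
#' @param epsilon minimum variation gain to accept a proposal (default 0,
#'   i.e. strict increase).
#' @param maxOps maximum number of coupled clone/merge events per
#'   resampling step. The default 1 executes the single best
#'   variation-increasing event each step, which keeps the lineage
#'   termination rate near one merge per cycle so that lag windows tens of
#'   cycles long retain surviving lineages; `0` repeats proposals until
#'   the variation reaches a local maximum (an aggressive regime that on
#'   the benchmark walk terminates most lineages within a few cycles).
#' @return a [RevoParams-class].
#' @export
revoParams <- function(mergeMode = c("lenient", "strict", "none"),
                       d0 = 0.25, alpha = 4, pMin = 1e-12, pMax = 0.1,
                       C = 100, mergeDist = NULL, epsilon = 0,
                       maxOps = 1L) {
  mergeMode <- match.arg(mergeMode)
  if (is.null(mergeDist))
    mergeDist <- switch(mergeMode, strict = 0, lenient = 1, none = 0)
  # Class must be named: an argument named `C` would otherwise partially
  # match new()'s `Class` formal
  new(Class = "RevoParams", d0 = d0, alpha = alpha, pMin = pMin,
      pMax = pMax, C = C, mergeMode = mergeMode, mergeDist = mergeDist,
      epsilon = epsilon, maxOps = as.integer(maxOps))
}

#' Novelty of a walker weight
#'
#' \eqn{\phi(w) = \log w - \log(p_{min}/C)} (natural log). The log base only
#' rescales the variation uniformly and cannot change which resampling
#' proposals are accepted.
#'
#' @param weight walker weight(s), > 0.
#' @param params a [RevoParams-class].
#' @return numeric novelty value(s).
#' @export
noveltyWeight <- function(weight, params) {
  stopifnot(all(weight > 0))
  log(weight) - log(params@pMin / params@C)
}

#' Absolute-difference metric for 1D discrete states
#'
#' The natural distance for the biased random walk: `|a - b|` in state units.
#'
#' @param a,b 0-based state indices (vectorized).
#' @return numeric distance(s).
#' @export
brwDistance <- function(a, b) abs(as.numeric(a) - as.numeric(b))

#' Trajectory variation of a walker ensemble
#'
#' \eqn{V = \sum_i \sum_{j \ne i} (d_{ij}/d_0)^\alpha \phi_i \phi_j}, the
#' objective the resampler greedily maximizes. Symmetric in walker order and
#' zero when all walkers coincide.
#'
#' @param states walker states (inputs to `distFun`).
#' @param weights walker weights.
#' @param params a [RevoParams-class].
#' @param distFun vectorized pairwise metric (default [brwDistance()]).
#' @return a single number.
#' @export
ensembleVariation <- function(states, weights, params,
                              distFun = brwDistance) {
  stopifnot(length(states) >= 2L, length(states) == length(weights))
  D <- (outer(states, states, distFun) / params@d0)^params@alpha
  diag(D) <- 0
  phi <- noveltyWeight(weights, params)
  as.numeric(phi %*% D %*% phi)
}


#' REVO resampling of a walker ensemble
#'
#' Proposes coupled clone/merge operations and executes each only if the
#' trajectory variation strictly increases (by at least `params@epsilon`,
#' with a small relative floating-point guard so exactly variation-neutral
#' swaps are not churned), stopping after `params@maxOps` executed events
#' (default one per step) or at a local maximum when `maxOps = 0`.
#' Each proposal clones, binarily, the as-yet-unsplit walker with the
#' largest individual contribution to the variation (among those whose
#' half-weight stays above `pMin`; a walker is cloned at most once per
#' resampling step) and squashes the unsplit eligible walker with the
#' *lowest* contribution into its nearest eligible partner (within
#' `mergeDist` under the merge mode, combined weight at most `pMax`, clone
#' candidate excluded). Positions are fixed for the whole step; the kept
#' conformation of each merge group is drawn at the end by the weight
#' lottery of [mergePair()]. Walker count and total weight are conserved
#' exactly; with `mergeMode = "none"` the resampler is the identity.
#'
#' @param states 0-based integer walker states.
#' @param weights walker weights (summing to 1).
#' @param params a [RevoParams-class].
#' @param distFun vectorized pairwise metric on states (default
#'   [brwDistance()]); evaluated once on the discrete state grid.
#' @param nStates number of discrete states (defaults to `max(states) + 1`).
#' @return a list with elements
#'   \describe{
#'     \item{states, weights}{the post-resampling ensemble (same length).}
#'     \item{origin}{for each output slot, the index of the input walker its
#'       lineage descends from.}
#'     \item{frac}{clone-division fraction of the input walker's weight the
#'       slot carries (merge gains excluded, so fractions of one input's
#'       surviving slots plus its squashed fractions sum to 1).}
#'     \item{squashes}{list of parallel vectors (`walker`, `frac`, `into`)
#'       describing lineages terminated by merging, indices referring to
#'       input walkers.}
#'     \item{nAccepted}{number of executed clone/merge proposals.}
#'     \item{blockedByPmax}{count of distance-eligible merge pairs that were
#'       blocked by the maximum weight threshold across proposals.}
#'     \item{deltaV}{total variation gain over the resampling step.}
#'   }
#' @export
revoResample <- function(states, weights, params, distFun = brwDistance,
                         nStates = NULL) {
  n0 <- length(states)
  stopifnot(length(weights) == n0, all(states >= 0L))
  if (params@mergeMode == "none" || n0 < 3L)
    return(list(states = states, weights = weights, origin = seq_len(n0),
                frac = rep(1, n0),
                squashes = list(walker = integer(), frac = numeric(),
                                into = integer()),
                nAccepted = 0L, blockedByPmax = 0L, deltaV = 0))
  if (is.null(nStates)) nStates <- max(states) + 1L
  lookup <- .distLookup(distFun, nStates)
  out <- .revoResampleCpp(as.integer(states), as.numeric(weights), lookup,
                          params@d0, params@alpha, params@pMin, params@pMax,
                          params@C, params@mergeDist, params@epsilon,
                          params@maxOps)
  if (!is.integer(states)) out$states <- as.numeric(out$states)
  out
}

# pairwise metric evaluated on the discrete state grid (0-based)
.distLookup <- function(distFun, nStates) {
  s <- seq_len(nStates) - 1L
  m <- outer(s, s, distFun)
  storage.mode(m) <- "double"
  m
}
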