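#' Merge two walkers
#'
#' The merged walker carries the summed weight `wA + wB` and adopts walker
#' A's state with probability `wA / (wA + wB)`, otherwise walker B's. This
#' weight lottery is what makes the expected flow of probability between any
#' two regions zero under resampling.
#'
#' @param a,b walkers as `list(state = , weight = )`, both weights > 0.
#' @return list with `walker` (the merged walker) and `keptA` (logical,
#'   whether A's state was adopted).
#' @export
mergePair <- function(a, b) {
  stopifnot(a$weight > 0, b$weight > 0)
  w <- a$weight + b$weight
  keptA <- stats::runif(1) < a$weight / w
  list(walker = list(state = if (keptA) a$state else b$state, weight = w),
       keptA = keptA)
}

#' Clone a walker into n copies
#'
#' Each clone adopts the parent's state and an even share `w / n` of its
#' weight, so the clone weights sum to the parent's weight exactly.
#'
#' @param w walker as `list(state = , weight = )`.
#' @param n number of copies (integer >= 1).
#' @param pMin minimum allowed clone weight; `n` is rejected if `w/n` would
#'   fall below it (default 0, no bound).
#' @return list of `n` walkers.
#' @export
cloneWalker <- function(w, n, pMin = 0) {
  n <- as.integer(n)
  stopifnot(n >= 1L)
  if (w$weight / n < pMin)
    stop(sprintf("cloning into %d drives weight %.3g below pMin = %.3g",
                 n, w$weight / n, pMin))
  replicate(n, list(state = w$state, weight = w$weight / n),
            simplify = FALSE)
}

# fate tags for the walkers of one cycle, given the resampling outcome;
# squashes is a list (or data.frame) with walker/frac/into components
.cycleFates <- function(n, origin, squashes) {
  childCount <- tabulate(origin, nbins = n)
  fate <- rep("CONTINUED", n)
  cloned <- childCount >= 2L
  fate[cloned] <- sprintf("CLONED(%d)", childCount[cloned])
  if (length(squashes$walker)) {
    for (k in unique(squashes$into)) {
      absorbed <- squashes$walker[squashes$into == k]
      tag <- sprintf("KEPT_MERGE(%s)", paste(absorbed, collapse = ","))
      fate[k] <- if (childCount[k] >= 2L)
        paste0(tag, "+", fate[k]) else tag
    }
    gone <- which(childCount == 0L)
    for (w in gone) {
      into <- squashes$into[match(w, squashes$walker)]
      fate[w] <- sprintf("SQUASHED(%d)", into)
    }
  }
  fate
}

#' Run a weighted-ensemble simulation
#'
#' Alternates one dynamics step for every walker (a draw from the chain's
#' transition matrix) with one REVO resampling step, recording the full
#' trajectory tree. The per-cycle snapshot — states and weights — is taken
#' after dynamics and *before* resampling, so one-step transitions are
#' complete even for lineages merged away immediately afterwards. No
#' resampling is performed after the final cycle.
#'
#' All walkers start in `initState` with weight `1 / nWalkers`; total weight
#' is checked every cycle and the run aborts if conservation drifts beyond
#' 1e-9.
#'
#' @param chain a [TransitionMatrix-class] (lag 1) to propagate under.
#' @param resampler `"lenient"`, `"strict"`, `"none"`, or a
#'   [RevoParams-class] used as-is.
#' @param nWalkers ensemble size (constant across cycles).
#' @param nCycles number of cycles to run.
#' @param seed optional integer; when given, seeds the RNG at the start of
#'   the run so identical configurations reproduce bit-identical trees.
#' @param initState 0-based starting state for all walkers (default 0).
#' @param distFun vectorized pairwise metric for REVO (default
#'   [brwDistance()]).
#' @param tauWE physical time per cycle (default 1).
#' @return a [TrajectoryTree-class].
#' @examples
#' tree <- runSimulation(buildBrwMatrix(), "lenient", nWalkers = 12,
#'                       nCycles = 50, seed = 1)
#' tree
#' @export
runSimulation <- function(chain, resampler = c("lenient", "strict", "none"),
                          nWalkers = 48L, nCycles = 6000L, seed = NULL,
                          initState = 0L, distFun = brwDistance, tauWE = 1) {
  stopifnot(is(chain, "TransitionMatrix"))
  if (is(resampler, "RevoParams")) {
    params <- resampler
    mode <- params@mergeMode
  } else {
    mode <- match.arg(resampler)
    params <- revoParams(mergeMode = mode)
  }
  nWalkers <- as.integer(nWalkers); nCycles <- as.integer(nCycles)
  stopifnot(nWalkers >= 1L, nCycles >= 1L)
  if (!is.null(seed)) set.seed(as.integer(seed))

  nS <- nrow(chain@probs)
  cumT <- apply(chain@probs, 2, cumsum)
  lookup <- .distLookup(distFun, nS)
  out <- .weRunCpp(cumT, nWalkers, nCycles, as.integer(initState), lookup,
                   params@d0, params@alpha, params@pMin, params@pMax,
                   params@C, params@mergeDist, params@epsilon,
                   resample = mode != "none", maxOps = params@maxOps)
  sq <- as.data.frame(out$squashes)
  if (nrow(sq) == 0L)
    sq <- data.frame(cycle = integer(), walker = integer(),
                     frac = numeric(), into = integer())
  fates <- .deriveFates(out$parents, sq, nCycles, nWalkers)
  new("TrajectoryTree", states = out$states, weights = out$weights,
      parents = out$parents, cloneFrac = out$cloneFrac,
      squashes = sq, fates = fates, tauWE = tauWE,
      meta = list(seed = seed, resampler = mode,
                  nStates = nS, initState = initState,
                  blockedByPmax = out$blockedByPmax,
                  params = list(d0 = params@d0, alpha = params@alpha,
                                pMin = params@pMin, pMax = params@pMax,
                                C = params@C, mergeDist = params@mergeDist,
                                epsilon = params@epsilon)))
}

# fate tags for all cycles at once from the parent maps and squash table
.deriveFates <- function(parents, squashes, nCycles, nWalkers) {
  Fa <- matrix("CONTINUED", nCycles, nWalkers)
  if (nCycles < 2L) return(Fa)
  # child counts: tabulate parents of cycle c+1 per cycle c
  cyc <- rep(seq_len(nCycles - 1L), nWalkers)
  cc <- matrix(tabulate((cyc - 1L) * nWalkers +
                          as.vector(parents[-1L, , drop = FALSE]),
                        nbins = (nCycles - 1L) * nWalkers),
               nCycles - 1L, nWalkers, byrow = TRUE)
  cloned <- which(cc >= 2L)
  if (length(cloned)) {
    Fa[seq_len(nCycles - 1L), ][cloned] <-
      sprintf("CLONED(%d)", cc[cloned])
  }
  if (nrow(squashes)) {
    keyKeep <- paste(squashes$cycle, squashes$into)
    absorbed <- vapply(split(squashes$walker, keyKeep),
                       paste, character(1), collapse = ",")
    keepCyc <- as.integer(sub(" .*", "", names(absorbed)))
    keepW <- as.integer(sub(".* ", "", names(absorbed)))
    base <- Fa[cbind(keepCyc, keepW)]
    tag <- sprintf("KEPT_MERGE(%s)", absorbed)
    tag <- ifelse(startsWith(base, "CLONED"),
                  paste0(tag, "+", base), tag)
    Fa[cbind(keepCyc, keepW)] <- tag
    gone <- cc[cbind(squashes$cycle, squashes$walker)] == 0L
    Fa[cbind(squashes$cycle[gone], squashes$walker[gone])] <-
      sprintf("SQUASHED(%d)", squashes$into[gone])
  }
  Fa
}
#' Assemble a trajectory tree from explicit matrices
#'
#' Low-level constructor for hand-built and fixture trees. When `cloneFrac`
#' is omitted it defaults to the even clone split implied by `parents` (a
#' parent with k children gives each a fraction `1/k`); when `fates` is
#' omitted it is derived from child counts and `squashes`.
#'
#' @param states,weights,parents `[cycle, walker]` matrices as in
#'   [TrajectoryTree-class].
#' @param cloneFrac optional clone-fraction matrix.
#' @param squashes optional data.frame (`cycle`, `walker`, `frac`, `into`).
#' @param tauWE physical time per cycle.
#' @param meta optional provenance list.
#' @return a [TrajectoryTree-class].
#' @export
makeTree <- function(states, weights, parents, cloneFrac = NULL,
                     squashes = NULL, tauWE = 1, meta = list()) {
  states <- as.matrix(states); weights <- as.matrix(weights)
  parents <- as.matrix(parents)
  nC <- nrow(states); nW <- ncol(states)
  if (is.null(squashes))
    squashes <- data.frame(cycle = integer(), walker = integer(),
                           frac = numeric(), into = integer())
  if (is.null(cloneFrac)) {
    cloneFrac <- matrix(1, nC, nW)
    if (nC > 1) for (cyc in 2:nC) {
      cc <- tabulate(parents[cyc, ], nbins = nW)
      cloneFrac[cyc, ] <- 1 / cc[parents[cyc, ]]
    }
  }
  fates <- matrix("CONTINUED", nC, nW)
  if (nC > 1) for (cyc in 1:(nC - 1)) {
    sq <- squashes[squashes$cycle == cyc, , drop = FALSE]
    fates[cyc, ] <- .cycleFates(nW, parents[cyc + 1, ], sq)
  }
  storage.mode(states) <- "integer"
  storage.mode(parents) <- "integer"
  new("TrajectoryTree", states = states,
      weights = weights, parents = parents,
      cloneFrac = cloneFrac, squashes = squashes, fates = fates,
      tauWE = tauWE, meta = meta)
}

#' Time-averaged state probabilities of a WE run
#'
#' Per-state average of walker weights over all cycles after `burnIn`,
#' normalized. This is the direct WE estimate of the steady-state
#' distribution.
#'
#' @param tree a [TrajectoryTree-class].
#' @param burnIn number of initial cycles to discard (default 0).
#' @param nStates number of states; defaults to the tree's metadata, else
#'   `max(state) + 1`.
#' @return named probability vector over states.
#' @export
weStateProbabilities <- function(tree, burnIn = 0L, nStates = NULL) {
  stopifnot(burnIn < nCycles(tree))
  if (is.null(nStates))
    nStates <- tree@meta$nStates %||% (max(tree@states) + 1L)
  rows <- (burnIn + 1L):nCycles(tree)
  idx <- as.vector(tree@states[rows, , drop = FALSE]) + 1L
  w <- as.vector(tree@weights[rows, , drop = FALSE])
  p <- vapply(split(w, factor(idx, levels = seq_len(nStates))),
              sum, numeric(1))
  p <- p / sum(p)
  names(p) <- paste0("s", seq_len(nStates) - 1L)
  p
}

#' Trace a walker's lineage back to the first cycle
#'
#' @param tree a [TrajectoryTree-class].
#' @param cycle,walker position to start from.
#' @return integer vector of walker indices at cycles `1..cycle`.
#' @export
traceLineage <- function(tree, cycle, walker) {
  path <- integer(cycle)
  path[cycle] <- walker
  if (cycle > 1) for (cyc in cycle:2)
    path[cyc - 1L] <- tree@parents[cyc, path[cyc]]
  path
}
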