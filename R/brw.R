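#' Construct a biased random walk specification
#'
#' The default is the 16-state benchmark: forward hop probability 0.25,
#' backward 0.75, a reflecting self-transition at state 0, and a warping
#' boundary that sends the forward move out of state 15 back to state 0.
#' Warping makes the chain a steady-state model of a unidirectional rare
#' event: the stationary flux through the boundary,
#' `P(n-1) * pFwd`, is the event rate.
#'
#' @param nStates number of discrete states (default 16).
#' @param pFwd forward hopping probability (default 0.25).
#' @param pBwd backward hopping probability (default `1 - pFwd`).
#' @param warp logical; route the last state's forward move to state 0
#'   (default `TRUE`).
#' @return a [ChainSpec-class].
#' @examples
#' chainSpec()
#' @export
chainSpec <- function(nStates = 16L, pFwd = 0.25, pBwd = 1 - pFwd,
                      warp = TRUE) {
  new("ChainSpec", nStates = as.integer(nStates), pFwd = pFwd, pBwd = pBwd,
      warp = warp)
}

#' Wrap a numeric matrix as a TransitionMatrix
#'
#' Validates the column-stochastic `[to, from]` convention and attaches
#' 0-based state labels as dimnames.
#'
#' @param probs square numeric matrix; `probs[k, j] = P(j -> k)`, columns
#'   summing to 1.
#' @param lag lag in resampling intervals (default 1).
#' @return a [TransitionMatrix-class].
#' @export
transitionMatrix <- function(probs, lag = 1L) {
  probs <- as.matrix(probs)
  lab <- paste0("s", seq_len(nrow(probs)) - 1L)
  dimnames(probs) <- list(to = lab, from = lab)
  new("TransitionMatrix", probs = probs, lag = as.integer(lag))
}

#' One-step transition matrix of the biased random walk
#'
#' Interior states hop `+1` with probability `pFwd` and `-1` with `pBwd`.
#' State 0's backward mass is a self-transition. The last state's forward
#' mass goes to state 0 when `warp` is set (the warp is part of the
#' integrator, a regular transition), otherwise it is a self-transition.
#'
#' @param spec a [ChainSpec-class].
#' @return a [TransitionMatrix-class] at lag 1.
#' @examples
#' T1 <- buildBrwMatrix(chainSpec())
#' probMatrix(T1)["s8", "s7"]  # 0.25
#' @export
buildBrwMatrix <- function(spec = chainSpec()) {
  stopifnot(is(spec, "ChainSpec"))
  validObject(spec)
  n <- spec@nStates
  P <- matrix(0, n, n)
  for (j in seq_len(n)) {
    fwd <- if (j < n) j + 1L else if (spec@warp) 1L else j
    bwd <- if (j > 1L) j - 1L else 1L
    P[fwd, j] <- P[fwd, j] + spec@pFwd
    P[bwd, j] <- P[bwd, j] + spec@pBwd
  }
  transitionMatrix(P, lag = 1L)
}

#' Stationary distribution of a column-stochastic matrix
#'
#' Computes the eigenvector of eigenvalue 1. Signals an error if no
#' eigenvalue lies within `1e-8` of 1 or if the eigenvalue-1 eigenspace has
#' dimension greater than 1 (no unique stationary distribution). Negative
#' components larger than `-1e-12` are clipped to zero and the vector
#' renormalized; anything more negative is an error.
#'
#' @param T a [TransitionMatrix-class] or a column-stochastic numeric matrix.
#' @return numeric probability vector `pi` with `T %*% pi = pi` to 1e-10.
#' @examples
#' pi <- analyticSteadyState(buildBrwMatrix())
#' sum(pi)  # 1
#' @export
analyticSteadyState <- function(T) {
  P <- if (is(T, "TransitionMatrix")) T@probs else as.matrix(T)
  e <- eigen(P)
  near1 <- which(abs(e$values - 1) < 1e-8)
  if (length(near1) == 0L)
    stop("no eigenvalue within 1e-8 of 1; matrix is not stochastic?")
  if (length(near1) > 1L)
    stop("eigenvalue-1 eigenspace has dimension > 1; ",
         "stationary distribution is not unique")
  v <- e$vectors[, near1]
  if (max(abs(Im(v))) > 1e-10)
    stop("stationary eigenvector has a non-negligible imaginary part")
  v <- Re(v)
  v <- v / sum(v)
  if (any(v < -1e-12))
    stop(sprintf("stationary eigenvector has negative component %.3g", min(v)))
  v[v < 0] <- 0
  v <- v / sum(v)
  resid <- max(abs(P %*% v - v))
  if (resid > 1e-10)
    stop(sprintf("fixed-point residual %.3g exceeds 1e-10", resid))
  names(v) <- colnames(P)
  v
}

#' Steady-state flux through the warping boundary
#'
#' The rate of the modelled rare event: the stationary probability of the
#' final state times the forward hopping probability, i.e. the per-step
#' probability of a warp (final state to state 0) transition.
#'
#' @param pi stationary probability vector.
#' @param spec the [ChainSpec-class] the chain was built from.
#' @return rate per step.
#' @export
boundaryRate <- function(pi, spec = chainSpec()) {
  stopifnot(abs(sum(pi) - 1) < 1e-6 || all(pi == 0))
  pi[spec@nStates] * spec@pFwd
}

#' Advance walkers one step through a discrete chain
#'
#' `stepWalkers` draws, for each walker, a destination from the origin's
#' column of `T` using the current RNG stream; `stepWalker` is the
#' single-walker convenience wrapper. States are 0-based labels.
#'
#' @param states integer vector of current 0-based states.
#' @param T a [TransitionMatrix-class].
#' @return integer vector (or scalar) of new 0-based states.
#' @examples
#' set.seed(1)
#' stepWalker(7L, buildBrwMatrix())
#' @export
stepWalkers <- function(states, T) {
  P <- T@probs
  n <- nrow(P)
  idx <- as.integer(states) + 1L
  stopifnot(all(idx >= 1L), all(idx <= n))
  cum <- apply(P, 2, cumsum)
  u <- stats::runif(length(idx))
  th <- cum[, idx, drop = FALSE]
  new_idx <- colSums(th < rep(u, each = n)) + 1L
  as.integer(new_idx - 1L)
}

#' @rdname stepWalkers
#' @param state a single 0-based state.
#' @export
stepWalker <- function(state, T) stepWalkers(state, T)[1L]

#' Read and write transition matrices as plain-text CSV
#'
#' The on-disk format is a CSV with a header row of 0-based state labels
#' and one row per destination state; values are decimal probabilities in
#' the column-stochastic `[to, from]` layout.
#'
#' @param path file path.
#' @param lag lag attached to the matrix on read (default 1).
#' @return `readTransitionMatrix` returns a [TransitionMatrix-class];
#'   `writeTransitionMatrix` returns `path` invisibly.
#' @export
readTransitionMatrix <- function(path, lag = 1L) {
  df <- utils::read.csv(path, check.names = FALSE)
  transitionMatrix(as.matrix(df), lag = lag)
}

#' @rdname readTransitionMatrix
#' @param T a [TransitionMatrix-class] to write.
#' @export
writeTransitionMatrix <- function(T, path) {
  stopifnot(is(T, "TransitionMatrix"))
  utils::write.csv(as.data.frame(T@probs), path, row.names = FALSE)
  invisible(path)
}

#' Construct a lag specification
#'
#' @param nTau lag in resampling intervals (integer >= 1).
#' @param tauWE physical time per resampling interval (default 1).
#' @return a [LagSpec-class].
#' @export
lagSpec <- function(nTau, tauWE = 1) {
  new("LagSpec", nTau = as.integer(nTau), tauWE = tauWE)
}
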