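#' Deterministic fixture trees with hand-checkable analyses
#'
#' Two tiny trajectory trees whose lag-window decompositions are known in
#' closed form, useful for validating window extraction and the
#' merging-bias correction:
#' \describe{
#'   \item{`fiveWalker`}{5 walkers, 5 cycles. Lineage A clones into two
#'     branches (absorbing lineage B by merging), lineage C clones into two
#'     (absorbing D), lineage E continues. At lag 4 there is a single
#'     window start and it yields exactly five transitions —
#'     (A1,A5), (A1,B5), (C1,C5), (C1,D5), (E1,E5) — plus two incomplete
#'     lineages (B squashed with 3 steps remaining, D with 2).}
#'   \item{`squashAfterOneStep`}{3 walkers, 3 cycles, lag 2. Walker B is
#'     squashed after a single step carrying weight 0.2, so M_1 holds the
#'     single entry 0.2 at `[state of B after the step, state of B at the
#'     start]`.}
#' }
#'
#' @return named list of [TrajectoryTree-class] objects.
#' @export
makeFixtureTrees <- function() {
  # fiveWalker: slots 1..5 are lineages A,B,C,D,E at cycle 1.
  # After cycle 2: B (slot 2) squashed into A, A cloned into slots 1+2.
  # After cycle 3: D (slot 4) squashed into C, C cloned into slots 3+4.
  states <- rbind(c(2L, 3L, 5L, 6L, 9L),
                  c(3L, 2L, 6L, 5L, 8L),
                  c(2L, 4L, 5L, 6L, 9L),
                  c(3L, 3L, 6L, 7L, 8L),
                  c(2L, 4L, 5L, 6L, 9L))
  weights <- matrix(0.2, 5, 5)
  parents <- rbind(c(0L, 0L, 0L, 0L, 0L),
                   c(1L, 2L, 3L, 4L, 5L),
                   c(1L, 1L, 3L, 4L, 5L),
                   c(1L, 2L, 3L, 3L, 5L),
                   c(1L, 2L, 3L, 4L, 5L))
  squashes <- data.frame(cycle = c(2L, 3L), walker = c(2L, 4L),
                         frac = c(1, 1), into = c(1L, 3L))
  fiveWalker <- makeTree(states, weights, parents, squashes = squashes,
                         meta = list(nStates = 10L, fixture = "fiveWalker"))

  # squashAfterOneStep: walker B (slot 2) takes one step, then is merged
  # into walker A; walker C is cloned to keep the count at 3.
  st2 <- rbind(c(0L, 1L, 3L),
               c(1L, 2L, 3L),
               c(0L, 3L, 4L))
  wt2 <- rbind(c(0.4, 0.2, 0.4),
               c(0.4, 0.2, 0.4),
               c(0.6, 0.2, 0.2))
  pa2 <- rbind(c(0L, 0L, 0L),
               c(1L, 2L, 3L),
               c(1L, 3L, 3L))
  sq2 <- data.frame(cycle = 2L, walker = 2L, frac = 1, into = 1L)
  squashAfterOneStep <- makeTree(st2, wt2, pa2, squashes = sq2,
                                 meta = list(nStates = 5L,
                                             fixture = "squashAfterOneStep"))
  list(fiveWalker = fiveWalker, squashAfterOneStep = squashAfterOneStep)
}

#' Random small trajectory tree for property testing
#'
#' Generates a valid trajectory tree by running random dynamics on a chain
#' and, between cycles, executing randomly chosen coupled merge/clone
#' operations with the exact WE weight rules (summed weight to the lottery
#' winner, even split across clones). This generator is deliberately
#' independent of the REVO resampler, so tree-analysis code can be checked
#' against bookkeeping oracles on trees whose branching is not REVO-shaped.
#'
#' @param seed integer seed.
#' @param nWalkers,nCycles tree dimensions.
#' @param nStates number of states of the uniform random dynamics.
#' @param opProb probability of attempting a merge/clone pair after each
#'   cycle (up to `maxOps` attempts).
#' @param maxOps maximum coupled operations per resampling step.
#' @return a [TrajectoryTree-class].
#' @export
randomFixtureTree <- function(seed, nWalkers = 4L, nCycles = 6L,
                              nStates = 4L, opProb = 0.7, maxOps = 2L) {
  set.seed(seed)
  N <- nWalkers
  st <- sample.int(nStates, N, replace = TRUE) - 1L
  wt <- rep(1 / N, N)
  S <- matrix(0L, nCycles, N); W <- matrix(0, nCycles, N)
  Pm <- matrix(0L, nCycles, N); Fr <- matrix(1, nCycles, N)
  sqAll <- list()
  nextParents <- rep(0L, N); nextFrac <- rep(1, N)
  for (cyc in seq_len(nCycles)) {
    st <- sample.int(nStates, N, replace = TRUE) - 1L  # uniform dynamics
    S[cyc, ] <- st; W[cyc, ] <- wt
    Pm[cyc, ] <- nextParents; Fr[cyc, ] <- nextFrac
    if (cyc < nCycles) {
      origin <- seq_len(N); frac <- rep(1, N)
      for (op in seq_len(maxOps)) {
        if (stats::runif(1) > opProb || N < 3L) break
        pair <- sample.int(N, 2L)
        mw <- mergePair(list(state = st[pair[1L]], weight = wt[pair[1L]]),
                        list(state = st[pair[2L]], weight = wt[pair[2L]]))
        kept <- if (mw$keptA) pair[1L] else pair[2L]
        gone <- setdiff(pair, kept)
        cl <- sample(setdiff(seq_len(N), pair), 1L)
        sqAll[[length(sqAll) + 1L]] <- data.frame(
          cycle = cyc, walker = origin[gone], frac = frac[gone],
          into = origin[kept])
        keep <- setdiff(seq_len(N), gone)
        wt[kept] <- mw$walker$weight
        st <- c(st[keep], st[cl]); wt2 <- wt[keep]
        clPos <- which(keep == cl)
        wt2[clPos] <- wt[cl] / 2
        wt <- c(wt2, wt[cl] / 2)
        fr2 <- frac[keep]; fr2[clPos] <- frac[cl] / 2
        frac <- c(fr2, frac[cl] / 2)
        origin <- c(origin[keep], origin[cl])
      }
      nextParents <- origin; nextFrac <- frac
    }
  }
  sq <- if (length(sqAll)) do.call(rbind, sqAll) else
    data.frame(cycle = integer(), walker = integer(), frac = numeric(),
               into = integer())
  makeTree(S, W, Pm, cloneFrac = Fr, squashes = sq,
           meta = list(nStates = nStates, fixture = "random", seed = seed))
}

#' Write the packaged fixture trees to a directory
#'
#' @param dir output directory (created if needed).
#' @return paths of the written JSON files, invisibly.
#' @export
writeFixtureTrees <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fx <- makeFixtureTrees()
  paths <- vapply(names(fx), function(nm) {
    writeTree(fx[[nm]], file.path(dir, paste0(nm, "_tree.json")))
  }, character(1))
  invisible(paths)
}
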