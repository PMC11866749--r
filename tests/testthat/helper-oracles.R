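# Independent oracles used across the suite. These deliberately use plain,
# brute-force algorithms (recursion over the tree, power iteration, direct
# per-anchor forward tables) so they share no code path with the package
# implementations they check.

# stationary distribution by long power iteration from the uniform vector
powerIterationSS <- function(P, iters = 10000L) {
  v <- rep(1 / nrow(P), nrow(P))
  for (i in seq_len(iters)) v <- as.vector(P %*% v)
  v / sum(v)
}

# Exhaustive enumeration of every lag-window lineage of a tree: walks the
# tree recursively from each window start, multiplying clone fractions by
# hand, and classifies each lineage as a complete transition (alive at the
# window end) or an incomplete one (terminated by a squash strictly inside
# the window). Returns both tables.
enumerateWindows <- function(tree, lag) {
  S <- treeStates(tree); W <- treeWeights(tree); P <- treeParents(tree)
  Fr <- treeCloneFrac(tree); sq <- treeSquashes(tree)
  Tn <- nCycles(tree); N <- nWalkers(tree)
  complete <- list(); incomplete <- list()
  for (s in seq_len(Tn - lag)) {
    for (w0 in seq_len(N)) {
      w1 <- W[s, w0]
      visit <- function(cyc, w, adjw) {
        if (cyc > s) {
          hit <- sq$cycle == cyc & sq$walker == w
          if (any(hit)) {
            for (f in sq$frac[hit]) {
              incomplete[[length(incomplete) + 1L]] <<- data.frame(
                start_cycle = s, i = s + lag - cyc,
                j = S[s, w0], k = S[cyc, w], w1 = w1, weight = adjw * f)
            }
          }
        }
        if (cyc == s + lag) {
          complete[[length(complete) + 1L]] <<- data.frame(
            start_cycle = s, start_state = S[s, w0],
            end_state = S[cyc, w], w1 = w1, w2 = adjw)
          return(invisible())
        }
        kids <- which(P[cyc + 1L, ] == w)
        for (k in kids) visit(cyc + 1L, k, adjw * Fr[cyc + 1L, k])
      }
      visit(s, w0, w1)
    }
  }
  list(
    complete = if (length(complete)) do.call(rbind, complete) else
      data.frame(start_cycle = integer(), start_state = integer(),
                 end_state = integer(), w1 = numeric(), w2 = numeric()),
    incomplete = if (length(incomplete)) do.call(rbind, incomplete) else
      data.frame(start_cycle = integer(), i = integer(), j = integer(),
                 k = integer(), w1 = numeric(), weight = numeric()))
}

# counts matrix assembled naively from an event data.frame
naiveCounts <- function(ev, nStates, mode = "w2") {
  C <- matrix(0, nStates, nStates)
  for (r in seq_len(nrow(ev))) {
    w <- if (mode == "w2") ev$w2[r] else ev$w2[r] / ev$w1[r]
    C[ev$end_state[r] + 1L, ev$start_state[r] + 1L] <-
      C[ev$end_state[r] + 1L, ev$start_state[r] + 1L] + w
  }
  C
}

# M_i matrices assembled naively from the oracle's incomplete table
naiveIncomplete <- function(inc, nStates, lag, mode = "w2") {
  M <- replicate(lag - 1L, matrix(0, nStates, nStates), simplify = FALSE)
  for (r in seq_len(nrow(inc))) {
    i <- inc$i[r]
    if (i < 1L || i > lag - 1L) next
    wt <- if (mode == "w2") inc$weight[r] else inc$weight[r] / inc$w1[r]
    M[[i]][inc$k[r] + 1L, inc$j[r] + 1L] <-
      M[[i]][inc$k[r] + 1L, inc$j[r] + 1L] + wt
  }
  M
}

# small default chain for engine tests: the 16-state benchmark walk
brwT1 <- function() buildBrwMatrix(chainSpec())
brwPi <- function() analyticSteadyState(brwT1())
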