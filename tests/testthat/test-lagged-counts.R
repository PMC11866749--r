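test_that("the five-walker fixture yields exactly the five printed transitions", {
  fx <- makeFixtureTrees()$fiveWalker
  ev <- slidingWindows(fx, 4)
  expect_equal(nrow(ev), 5L)
  expect_true(all(ev$start_cycle == 1L))
  S <- treeStates(fx)
  # lineages A (slots 1+2), C (slots 3+4), E (slot 5) at the window end
  expect_equal(sort(paste(ev$start_state, ev$end_state)),
               sort(paste(S[1, c(1, 1, 3, 3, 5)], S[5, ])))
  # two incomplete lineages: B squashed with 3 steps left, D with 2
  M <- collectIncomplete(fx, 4)
  sums <- vapply(M@M, sum, numeric(1))
  expect_equal(sums, c(0, 0.2, 0.2), tolerance = 1e-12)
  expect_equal(M@M[[3]][S[2, 2] + 1L, S[1, 2] + 1L], 0.2)
  expect_equal(M@M[[2]][S[3, 4] + 1L, S[1, 4] + 1L], 0.2)
})

test_that("a lineage squashed after one step lands in M_1 with its weight", {
  fx <- makeFixtureTrees()$squashAfterOneStep
  M <- collectIncomplete(fx, 2)
  S <- treeStates(fx)
  expect_equal(sum(M@M[[1]]), 0.2)
  expect_equal(M@M[[1]][S[2, 2] + 1L, S[1, 2] + 1L], 0.2)
})

test_that("window counts on merge-free trees equal independent-trajectory extraction", {
  T1 <- buildBrwMatrix()
  tree <- runSimulation(T1, "none", nWalkers = 6, nCycles = 40, seed = 5)
  for (lag in c(1, 3, 7)) {
    ev <- slidingWindows(tree, lag)
    expect_equal(nrow(ev), 6 * (40 - lag))
    expect_equal(ev$w1, ev$w2)
    expect_true(all(ev$w1 == 1 / 6))
    S <- treeStates(tree)
    # direct extraction: each walker is an independent trajectory
    expect_equal(sort(paste(ev$start_state, ev$end_state)),
                 sort(paste(as.vector(S[1:(40 - lag), ]),
                            as.vector(S[(lag + 1):40, ]))))
  }
  expect_error(slidingWindows(tree, 0), "nTau")
})

test_that("windows and incompletes partition every launched lineage (random trees)", {
  for (seed in 1:12) {
    tree <- randomFixtureTree(seed, nWalkers = 4L, nCycles = 6L)
    for (lag in c(2, 3, 4)) {
      oracle <- enumerateWindows(tree, lag)
      ev <- slidingWindows(tree, lag)
      # complete events match the recursive enumeration exactly
      key <- function(d) {
        k <- paste(d$start_cycle, d$start_state, d$end_state,
                   signif(d$w1, 12), signif(d$w2, 12))
        sort(k)
      }
      expect_equal(key(ev), key(oracle$complete))
      # incomplete matrices match the enumeration
      M <- collectIncomplete(tree, lag)
      Mo <- naiveIncomplete(oracle$incomplete, 4L, lag)
      for (i in seq_len(lag - 1))
        expect_equal(unname(M@M[[i]]), Mo[[i]], tolerance = 1e-12)
    }
  }
})

test_that("adjusted start weight is conserved across survivors and squashes", {
  for (seed in 13:20) {
    tree <- randomFixtureTree(seed, nWalkers = 5L, nCycles = 7L)
    lag <- 3
    ev <- slidingWindows(tree, lag)
    M <- collectIncomplete(tree, lag)
    nS <- 4L
    Cobs <- countMatrix(countsObserved(ev, nS, "w2"))
    # per start state: observed colsums + correction colsums = launched
    # adjusted weight, i.e. the clone fractions of each start walker that
    # survive the start cycle's resampling (a branch squashed right at the
    # start is never launched)
    launched <- numeric(nS)
    P <- treeParents(tree); S <- treeStates(tree); W <- treeWeights(tree)
    Fr <- treeCloneFrac(tree)
    for (s in seq_len(nCycles(tree) - lag)) {
      for (w in seq_len(nWalkers(tree))) {
        kids <- which(P[s + 1L, ] == w)
        if (length(kids)) {
          j <- S[s, w] + 1L
          launched[j] <- launched[j] + W[s, w] * sum(Fr[s + 1L, kids])
        }
      }
    }
    total <- colSums(Cobs) + Reduce(`+`, lapply(M@M, colSums))
    expect_equal(unname(total), launched, tolerance = 1e-10)
  }
})

test_that("adjusted weight tables divide on cloning and never gain on merging", {
  tree <- makeFixtureTrees()$fiveWalker
  adj <- adjustedWeightTable(tree, 1)
  expect_true(all(is.finite(adj)))
  # A's lineage halves at the clone after cycle 2
  expect_equal(adj[3, 1], 0.1); expect_equal(adj[3, 2], 0.1)
  # the kept walker of the merge keeps its own adjusted weight
  expect_equal(adj[5, 5], 0.2)
  # anchoring later restarts from the recorded weights
  adj3 <- adjustedWeightTable(tree, 3)
  expect_true(all(is.na(adj3[1:2, ])))
  expect_equal(adj3[3, ], treeWeights(tree)[3, ], ignore_attr = TRUE)
  # no-resampling tree: table constant in time
  flat <- runSimulation(buildBrwMatrix(), "none", 4, 10, seed = 2)
  a <- adjustedWeightTable(flat, 1)
  expect_true(all(a == 0.25))
})

test_that("adjusted tables agree with the log-cumulative fast path on REVO trees", {
  T1 <- buildBrwMatrix()
  tree <- runSimulation(T1, "lenient", 12, 60, seed = 9)
  lag <- 5
  ev <- slidingWindows(tree, lag)
  # recompute each event's w2 from a per-anchor forward table
  for (s in unique(ev$start_cycle)[1:10]) {
    adj <- adjustedWeightTable(tree, s)
    sub <- ev[ev$start_cycle == s, ]
    A <- treeParents(tree)
    for (rr in seq_len(nrow(sub))) {
      # walk back from the window end to find the leaf slot
      # (re-derive: all walkers at cycle s+lag whose ancestor matches)
      t_ <- s + lag
      anc <- vapply(seq_len(nWalkers(tree)),
                    function(w) traceLineage(tree, t_, w)[s], integer(1))
      leafW2 <- adj[t_, ]
      stS <- treeStates(tree)[s, anc]
      endS <- treeStates(tree)[t_, ]
      key <- paste(stS, endS, signif(leafW2, 12))
      expect_true(paste(sub$start_state[rr], sub$end_state[rr],
                        signif(sub$w2[rr], 12)) %in% key)
    }
  }
})

test_that("merging-bias histograms skew downhill from a mid-chain start", {
  T1 <- buildBrwMatrix()
  pi <- analyticSteadyState(T1)
  trees <- lapply(1:3, function(s)
    runSimulation(T1, "lenient", 48, 2000, seed = 300 + s))
  h <- rowMeans(vapply(trees, mergingBiasHistogram, numeric(16),
                       startState = 7, lag = 1))
  expect_equal(sum(h), 1, tolerance = 1e-12)
  # analytic one-step from state 7: 0.75 down, 0.25 up; squashed lineages
  # concentrate on the downhill side beyond the analytic share
  expect_gt(h[7], 0.75)
  expect_error(mergingBiasHistogram(
    runSimulation(T1, "none", 4, 20, seed = 1), 7, 1), "no merged-away")
})
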