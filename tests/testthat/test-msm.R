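test_that("counts accumulate events by mode and are order-invariant", {
  ev <- data.frame(start_cycle = 1L, start_state = 3L, end_state = 4L,
                   w1 = 0.5, w2 = 0.5)
  attr(ev, "lag") <- 2L
  C <- countsObserved(ev, 6, "w2")
  expect_equal(countMatrix(C)[5, 4], 0.5)
  expect_equal(sum(countMatrix(C)), 0.5)
  Cr <- countsObserved(ev, 6, "w2_over_w1")
  expect_equal(countMatrix(Cr)[5, 4], 1)
  # a lineage cloned into 4 by the window end contributes 1/4 per copy in
  # ratio mode
  ev4 <- data.frame(start_cycle = 1L, start_state = 0L,
                    end_state = c(1L, 1L, 2L, 0L),
                    w1 = 0.2, w2 = 0.05)
  attr(ev4, "lag") <- 3L
  C4 <- countsObserved(ev4, 3, "w2_over_w1")
  expect_equal(sum(countMatrix(C4)), 1)
  expect_equal(countMatrix(C4)[2, 1], 0.5)
  # permuting events leaves the matrix unchanged
  evp <- ev4[c(3, 1, 4, 2), ]
  attr(evp, "lag") <- 3L
  expect_equal(countMatrix(countsObserved(evp, 3, "w2_over_w1")),
               countMatrix(C4))
  # mixed lags are rejected
  ev2 <- ev; attr(ev2, "lag") <- 5L
  expect_error(countsObserved(list(ev, ev2), 6), "mixed lags")
})

test_that("one-step matrix from unresampled data matches the chain", {
  # a 6-state walk so straightforward dynamics visit every state
  spec6 <- chainSpec(nStates = 6L)
  T1 <- buildBrwMatrix(spec6)
  tree <- runSimulation(T1, "none", nWalkers = 50, nCycles = 2000, seed = 17)
  Th <- oneStepMatrix(tree)
  P <- probMatrix(T1); Ph <- probMatrix(Th)
  ev <- slidingWindows(tree, 1)
  nPer <- table(factor(ev$start_state, levels = 0:5))
  for (j in which(nPer > 200)) {
    for (k in which(P[, j] > 0)) {
      se <- sqrt(P[k, j] * (1 - P[k, j]) / nPer[j])
      expect_lt(abs(Ph[k, j] - P[k, j]), 4 * se + 1e-12)
    }
  }
  # one-step estimates from merged (lenient) data are complete too: the
  # estimator converges on the same chain. Ratio (duplication-only)
  # counting gives near-multinomial statistics per column, unlike w2
  # weighting whose heavy-tailed weights dominate single columns.
  T1 <- buildBrwMatrix()
  trees <- lapply(18:20, function(s)
    runSimulation(T1, "lenient", 48, 3000, seed = s))
  Th2 <- probMatrix(oneStepMatrix(trees, "w2_over_w1", nStates = 16))
  # forward hop probability out of mid-chain states
  for (j in 4:9) expect_lt(abs(Th2[j + 2, j + 1] - 0.25), 0.05)
})

test_that("deterministic chains give exact permutation one-step matrices", {
  P <- matrix(0, 3, 3); P[2, 1] <- 1; P[3, 2] <- 1; P[1, 3] <- 1
  tree <- runSimulation(transitionMatrix(P), "none", 4, 30, seed = 2)
  expect_equal(probMatrix(oneStepMatrix(tree)), P, ignore_attr = TRUE)
})

test_that("the corrected counts add exactly the squashed weight per column", {
  fx <- makeFixtureTrees()$squashAfterOneStep
  ev <- slidingWindows(fx, 2)
  Cobs <- countsObserved(ev, 5, "w2")
  T1h <- transitionMatrix(matrix(c(0, 1, 0, 0, 0,
                                   0, 0, 1, 0, 0,
                                   0, 0, 0, 1, 0,
                                   0, 0, 0, 0, 1,
                                   1, 0, 0, 0, 0), 5, 5))
  M <- collectIncomplete(fx, 2)
  C <- mbcCounts(Cobs, T1h, M)
  added <- countMatrix(C) - countMatrix(Cobs)
  # the whole squashed weight (0.2) lands back in B's start column
  expect_equal(colSums(added), c(0, 0.2, 0, 0, 0), ignore_attr = TRUE)
  expect_equal(sum(added), 0.2, tolerance = 1e-12)
})

test_that("corrected counts match exhaustive lineage completion on a forced merge", {
  # 3-state chain; walker B squashed after one step of a lag-2 window.
  # Completing B's lineage under T1 for the remaining step by hand:
  # C = C_obs + T1 %*% M_1.
  P <- matrix(c(0.6, 0.4, 0.0,
                0.2, 0.5, 0.3,
                0.0, 0.3, 0.7), 3, 3)  # columns j = 1..3
  T1h <- transitionMatrix(P)
  st <- rbind(c(0L, 1L, 2L), c(0L, 2L, 2L), c(1L, 2L, 0L))
  wt <- rbind(c(0.5, 0.25, 0.25), c(0.5, 0.25, 0.25), c(0.5, 0.375, 0.125))
  pa <- rbind(c(0L, 0L, 0L), c(1L, 2L, 3L), c(1L, 3L, 3L))
  sq <- data.frame(cycle = 2L, walker = 2L, frac = 1, into = 1L)
  tree <- makeTree(st, wt, pa, squashes = sq, meta = list(nStates = 3L))
  ev <- slidingWindows(tree, 2)
  Cobs <- countMatrix(countsObserved(ev, 3, "w2"))
  M <- collectIncomplete(tree, 2)
  C <- countMatrix(mbcCounts(countsObserved(ev, 3, "w2"), T1h, M))
  # by hand: B (weight 0.25, state 1 -> 2) is completed from state 2:
  # P[, 3] = (0, 0.3, 0.7)
  expect_equal(C - Cobs,
               0.25 * cbind(0, c(0, 0.3, 0.7), 0), ignore_attr = TRUE)
  # conservation: column sums of C equal column sums of C_obs plus the
  # squashed weight per start column
  expect_equal(colSums(C), colSums(Cobs) + c(0, 0.25, 0),
               ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("corrected and standard counts coincide on merge-free trees at every lag", {
  T1 <- buildBrwMatrix(chainSpec(nStates = 4L))
  tree <- runSimulation(T1, "none", 6, 200, seed = 4)
  T1h <- oneStepMatrix(tree)
  for (lag in c(2, 5, 10)) {
    Cobs <- countsObserved(slidingWindows(tree, lag), 4, "w2")
    M <- collectIncomplete(tree, lag)
    expect_true(all(vapply(M@M, function(m) all(m == 0), logical(1))))
    C <- mbcCounts(Cobs, T1h, M)
    expect_equal(countMatrix(C), countMatrix(Cobs), tolerance = 1e-14)
  }
})

test_that("normalizing counts recovers scale-invariant models and flags empty columns", {
  T1 <- buildBrwMatrix()
  P <- probMatrix(T1)
  C <- new("CountsMatrix", counts = P * 100, lag = lagSpec(1), mode = "w2")
  m <- msmFromCounts(C)
  expect_equal(probMatrix(m@transition), P, ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(unname(stationaryDist(m)),
               unname(analyticSteadyState(T1)), tolerance = 1e-10)
  bad <- P * 100; bad[, 3] <- 0
  Cb <- new("CountsMatrix", counts = bad, lag = lagSpec(1), mode = "w2")
  expect_error(msmFromCounts(Cb), "s2")
})

test_that("RMSLE follows its closed form", {
  expect_equal(rmsle(c(0.5, 0.5), c(0.5, 0.5)), 0)
  p <- c(0.2, 0.3, 0.5)
  expect_equal(rmsle(10 * p, p), 1)
  expect_equal(rmsle(c(0.9, 0.1), c(0.09, 0.91)),
               sqrt((log10(0.9 / 0.09)^2 + log10(0.1 / 0.91)^2) / 2),
               tolerance = 1e-14)
  expect_error(rmsle(p, c(0.5, 0.5, 0)), "strictly positive")
  expect_warning(r <- rmsle(c(0, 1), c(0.5, 0.5)), "floored")
  expect_equal(r, sqrt((log10(1e-16 / 0.5)^2 + log10(2)^2) / 2))
})

test_that("MFPT solves the absorbing-chain system and matches the flux", {
  spec <- chainSpec()
  T1 <- buildBrwMatrix(spec)
  pi <- analyticSteadyState(T1)
  # source in the sink set
  expect_equal(mfpt(T1, sinks = 0, source = 0), 0)
  # 2-state chain with escape probability p: MFPT = 1/p
  for (p in c(0.1, 0.25, 0.8)) {
    P2 <- matrix(c(1 - p, p, 0, 1), 2, 2)
    expect_equal(mfpt(transitionMatrix(P2), sinks = 1, source = 0), 1 / p,
                 tolerance = 1e-12)
  }
  # warp-event MFPT from state 0 equals the inverse boundary flux: add a
  # virtual absorbing state fed by the warp transition
  P <- probMatrix(T1)
  Pa <- matrix(0, 17, 17)
  Pa[1:16, 1:16] <- P
  Pa[1, 16] <- 0   # redirect the warp move to the absorber
  Pa[17, 16] <- 0.25
  Pa[17, 17] <- 1
  tWarp <- mfpt(transitionMatrix(Pa), sinks = 16, source = 0)
  expect_lt(abs(tWarp - 1 / boundaryRate(pi, spec)) * boundaryRate(pi, spec),
            0.01)
  # unreachable sinks are an error
  Pd <- diag(2)
  expect_error(mfpt(transitionMatrix(Pd), sinks = 1, source = 0),
               "unreachable")
})

test_that("CSN export filters edges by probability and never emits self-loops", {
  P <- matrix(c(0.99, 0.01, 0,
                0.004, 0.986, 0.01,
                0, 0.2, 0.8), 3, 3)
  Tt <- transitionMatrix(P)
  g <- exportCsn(Tt, edgeThreshold = 0.005)
  ed <- igraph::as_edgelist(g)
  # entries > 0.005 off-diagonal: [2,1]=0.01, [3,2]=0.01, [2,3]=0.2
  expect_equal(nrow(ed), 3)
  expect_false(any(ed[, 1] == ed[, 2]))
  expect_equal(igraph::ecount(exportCsn(Tt, edgeThreshold = 1)), 0)
  # node attributes carry the stationary weight and user scalars
  g2 <- exportCsn(Tt, nodeValues = list(rmsd = c(0.1, 0.5, 0.9)))
  expect_equal(igraph::V(g2)$rmsd, c(0.1, 0.5, 0.9))
  expect_equal(sum(igraph::V(g2)$stationary), 1, tolerance = 1e-9)
  # GraphML round trip
  path <- withr::local_tempfile(fileext = ".graphml")
  exportCsn(Tt, path = path)
  g3 <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::ecount(g3), 3)
})

test_that("lag-1 models are identical with and without the correction", {
  T1 <- buildBrwMatrix()
  tree <- runSimulation(T1, "lenient", 24, 500, seed = 12)
  ev <- slidingWindows(tree, 1)
  C <- countsObserved(ev, 16, "w2")
  m <- msmFromCounts(C, kind = "standard")
  expect_error(collectIncomplete(tree, 1), "nTau")
  # the corrected model at lag 1 is the standard model by construction:
  # there are no incomplete windows to complete
  expect_equal(stationaryDist(msmFromCounts(C, kind = "mbc")),
               stationaryDist(m))
})
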