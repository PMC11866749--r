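#' Configuration for a replicate WE + MSM benchmark experiment
#'
#' Bundles everything [runExperiment()] needs: the chain, the resampling
#' mode(s), replicate/ensemble sizes, the lag grid, the counting mode and
#' the base seed. Defaults reproduce the benchmark study: 10 runs of 6000
#' cycles with 48 walkers on the 16-state biased random walk, lags
#' 1–100.
#'
#' @param chain a [ChainSpec-class] (default the 16-state walk).
#' @param resamplers character vector of merge modes to run
#'   (subset of `"lenient"`, `"strict"`, `"none"`).
#' @param nRuns replicate runs per resampler (default 10).
#' @param nWalkers walkers per run (default 48).
#' @param nCycles cycles per run (default 6000).
#' @param lags integer lag grid (default `c(1, 5, 10, 25, 50, 75, 100)`).
#' @param mode counting mode, `"w2"` (default) or `"w2_over_w1"`.
#' @param baseSeed integer base seed; run r of resampler s uses seed
#'   `baseSeed + (s - 1) * nRuns + (r - 1)`.
#' @param burnIn cycles discarded from direct-WE averages (default 0).
#' @param checkpoints cycle counts at which direct-WE convergence is
#'   evaluated; `NULL` disables convergence curves.
#' @param msmConvergence logical; also rebuild MSMs at each checkpoint
#'   (costly; default `FALSE`).
#' @return a named list with class `"mbcmsmExperimentConfig"`.
#' @export
experimentConfig <- function(chain = chainSpec(),
                             resamplers = c("lenient", "strict", "none"),
                             nRuns = 10L, nWalkers = 48L, nCycles = 6000L,
                             lags = c(1L, 5L, 10L, 25L, 50L, 75L, 100L),
                             mode = c("w2", "w2_over_w1"),
                             baseSeed = 1L, burnIn = 0L,
                             checkpoints = c(250L, 500L, 1000L, 1500L,
                                             2000L, 3000L, 4000L, 6000L),
                             msmConvergence = FALSE) {
  mode <- match.arg(mode)
  resamplers <- match.arg(resamplers, c("lenient", "strict", "none"),
                          several.ok = TRUE)
  lags <- sort(unique(as.integer(lags)))
  stopifnot(all(lags >= 1L), max(lags) <= nCycles - 1L, nRuns >= 1L)
  if (!is.null(checkpoints))
    checkpoints <- sort(unique(pmin(as.integer(checkpoints), nCycles)))
  structure(list(chain = chain, resamplers = resamplers,
                 nRuns = as.integer(nRuns), nWalkers = as.integer(nWalkers),
                 nCycles = as.integer(nCycles), lags = lags, mode = mode,
                 baseSeed = as.integer(baseSeed), burnIn = as.integer(burnIn),
                 checkpoints = checkpoints,
                 msmConvergence = isTRUE(msmConvergence)),
            class = "mbcmsmExperimentConfig")
}

# first `m` cycles of a tree as a self-contained tree
.treeHead <- function(tree, m) {
  stopifnot(m >= 1L, m <= nCycles(tree))
  sq <- tree@squashes
  makeTree(tree@states[seq_len(m), , drop = FALSE],
           tree@weights[seq_len(m), , drop = FALSE],
           tree@parents[seq_len(m), , drop = FALSE],
           cloneFrac = tree@cloneFrac[seq_len(m), , drop = FALSE],
           squashes = sq[sq$cycle < m, , drop = FALSE],
           tauWE = tree@tauWE, meta = tree@meta)
}

.finalStateStats <- function(p, piRef) {
  n <- length(piRef)
  est <- p[n]
  err <- abs(log10(max(est, 1e-16)) - log10(piRef[n]))
  list(finalProb = unname(est), absLog10Err = unname(err))
}

# direct-WE and per-lag MSM statistics for one tree
.runStats <- function(tree, cfg, piRef, resampler, run) {
  nS <- length(piRef)
  pWE <- weStateProbabilities(tree, burnIn = cfg$burnIn, nStates = nS)
  fs <- .finalStateStats(pWE, piRef)
  weRow <- data.frame(resampler = resampler, run = run, lag = NA_integer_,
                      model = "we",
                      rmsle = suppressWarnings(rmsle(pWE, piRef)),
                      finalProb = fs$finalProb,
                      absLog10Err = fs$absLog10Err)
  msmRows <- lapply(cfg$lags, function(lg) {
    tryCatch({
      ev <- slidingWindows(tree, lg)
      Cobs <- countsObserved(ev, nS, cfg$mode)
      std <- msmFromCounts(Cobs, kind = "standard")
      if (lg >= 2L) {
        T1 <- oneStepMatrix(tree, cfg$mode, nStates = nS)
        M <- collectIncomplete(tree, lg, cfg$mode, nStates = nS)
        mbc <- msmFromCounts(mbcCounts(Cobs, T1, M), kind = "mbc")
      } else mbc <- std
      do.call(rbind, lapply(list(std, mbc), function(mod) {
        pf <- .finalStateStats(stationaryDist(mod), piRef)
        data.frame(resampler = resampler, run = run, lag = lg,
                   model = mod@provenance$kind,
                   rmsle = suppressWarnings(
                     rmsle(stationaryDist(mod), piRef)),
                   finalProb = pf$finalProb, absLog10Err = pf$absLog10Err)
      }))
    }, error = function(e) {
      warning(sprintf("run %d lag %d (%s): %s", run, lg, resampler,
                      conditionMessage(e)))
      data.frame(resampler = resampler, run = run,
                 lag = rep(lg, 2L), model = c("standard", "mbc"),
                 rmsle = NA_real_, finalProb = NA_real_,
                 absLog10Err = NA_real_)
    })
  })
  rbind(weRow, do.call(rbind, msmRows))
}

#' Run the replicate WE + MSM benchmark experiment
#'
#' For each resampler mode and replicate run: simulates the weighted
#' ensemble, computes direct-WE steady-state statistics (RMSLE over all
#' states against the analytic distribution, final-state probability and
#' its absolute log10 error), and for every lag in the grid builds both the
#' standard and the merging-bias-corrected MSM and records the same
#' statistics from their stationary distributions. Direct-WE convergence
#' versus cycles used is evaluated at the configured checkpoints.
#'
#' Identical configurations and base seed give bit-identical outputs.
#'
#' @param config an [experimentConfig()].
#' @param keepTrees logical; also return the trajectory trees (memory-heavy
#'   for full-size runs; default `FALSE`).
#' @return a list with
#'   \describe{
#'     \item{summary}{per run / lag / model-type statistics (model `"we"`
#'       rows carry `lag = NA`).}
#'     \item{aggregate}{cross-run mean and standard error (n-1 denominator)
#'       per resampler / lag / model.}
#'     \item{convergence}{direct-WE (and optionally MSM) statistics at each
#'       checkpoint.}
#'     \item{analytic}{the analytic stationary distribution used as
#'       reference.}
#'     \item{trees}{the trees, when `keepTrees = TRUE`.}
#'   }
#' @export
runExperiment <- function(config, keepTrees = FALSE) {
  stopifnot(inherits(config, "mbcmsmExperimentConfig"))
  T1chain <- buildBrwMatrix(config$chain)
  piRef <- analyticSteadyState(T1chain)
  rows <- list(); conv <- list(); trees <- list()
  for (si in seq_along(config$resamplers)) {
    rs <- config$resamplers[si]
    for (r in seq_len(config$nRuns)) {
      seed <- config$baseSeed + (si - 1L) * config$nRuns + (r - 1L)
      tree <- runSimulation(T1chain, rs, config$nWalkers, config$nCycles,
                            seed = seed)
      rows[[length(rows) + 1L]] <-
        .runStats(tree, config, piRef, rs, r)
      if (!is.null(config$checkpoints)) {
        for (m in config$checkpoints) {
          if (m > nCycles(tree)) next
          sub <- if (m == nCycles(tree)) tree else .treeHead(tree, m)
          if (config$msmConvergence && m > max(config$lags)) {
            st <- .runStats(sub, config, piRef, rs, r)
            st$cyclesUsed <- m
            conv[[length(conv) + 1L]] <- st
          } else {
            p <- weStateProbabilities(sub, burnIn = config$burnIn,
                                      nStates = length(piRef))
            fsc <- .finalStateStats(p, piRef)
            conv[[length(conv) + 1L]] <- data.frame(
              resampler = rs, run = r, lag = NA_integer_, model = "we",
              rmsle = suppressWarnings(rmsle(p, piRef)),
              finalProb = fsc$finalProb, absLog10Err = fsc$absLog10Err,
              cyclesUsed = m)
          }
        }
      }
      if (keepTrees) trees[[sprintf("%s_%d", rs, r)]] <- tree
    }
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  convergence <- if (length(conv)) do.call(rbind, conv) else NULL
  if (!is.null(convergence)) rownames(convergence) <- NULL
  out <- list(summary = summary,
              aggregate = aggregateExperiment(summary),
              convergence = convergence, analytic = piRef)
  if (keepTrees) out$trees <- trees
  out
}

#' Cross-run means and standard errors of experiment statistics
#'
#' @param summary the per-run table from [runExperiment()].
#' @return data.frame with one row per (resampler, lag, model) and columns
#'   `<stat>_mean` / `<stat>_se` (standard error with n-1 denominator).
#' @export
aggregateExperiment <- function(summary) {
  # direct-WE rows carry lag = NA; keep them as their own group
  lagKey <- ifelse(is.na(summary$lag), "direct", as.character(summary$lag))
  key <- paste(summary$resampler, lagKey, summary$model)
  agg <- lapply(split(summary, key), function(g) {
    se <- function(x) {
      x <- x[is.finite(x)]
      if (length(x) < 2L) return(NA_real_)
      stats::sd(x) / sqrt(length(x))
    }
    mn <- function(x) mean(x[is.finite(x)])
    data.frame(resampler = g$resampler[1L], lag = g$lag[1L],
               model = g$model[1L], n = nrow(g),
               rmsle_mean = mn(g$rmsle), rmsle_se = se(g$rmsle),
               finalProb_mean = mn(g$finalProb),
               finalProb_se = se(g$finalProb),
               absLog10Err_mean = mn(g$absLog10Err),
               absLog10Err_se = se(g$absLog10Err))
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out[order(out$resampler, out$model, out$lag, na.last = FALSE), ]
}
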