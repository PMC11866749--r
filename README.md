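# mbcmsm

Merging-bias-corrected Markov state models from weighted-ensemble
simulation data.

Weighted-ensemble (WE) methods sample rare events by propagating an
ensemble of *walkers* that carry statistical weights: walkers in
undersampled regions are cloned (weight split evenly), walkers in
oversampled regions are merged (one walker keeps the summed weight, the
kept conformation drawn in proportion to weight). The branched record of
every state, weight, parent and clone/merge fate is the *trajectory
tree*. Markov state models (MSMs) built from such trees at lag times
longer than one resampling interval systematically undercount transitions
whose lineages were terminated by merging inside the lag window — the
*merging bias*. This package is for WE practitioners and method developers
who need bias-aware MSM estimates and reproducible discrete-state
benchmarks.

The package provides

* a WE engine for discrete-state chains with the REVO
  (variation-optimization) resampler, recording full trajectory trees:
  `runSimulation()`, `revoResample()`;
* lag-window analysis of trees: `slidingWindows()`,
  `adjustedWeightTable()`, `collectIncomplete()`,
  `mergingBiasHistogram()`;
* MSM estimation with and without the merging-bias correction

  C(τ) = C_obs(τ) + Σ_{i=1..n_τ−1} T^i M_i,

  where T is the (bias-free) one-step matrix, and M_i holds the weights of
  lineages squashed with i resampling intervals left in the window:
  `countsObserved()`, `oneStepMatrix()`, `mbcCounts()`,
  `msmFromCounts()`;
* steady states, fluxes, mean first passage times, RMSLE and
  conformation-space-network export: `analyticSteadyState()`,
  `boundaryRate()`, `mfpt()`, `rmsle()`, `exportCsn()`;
* the analytically solvable benchmark — a 16-state biased random walk
  with forward hop probability 0.25, backward 0.75 and a warping boundary
  (state 15's forward move re-enters state 0) — plus a replicate
  experiment driver: `buildBrwMatrix()`, `runExperiment()`.

All matrices are column-stochastic with columns indexing the origin state
(`[to, from]`); state labels are 0-based.

## Worked example

```r
library(mbcmsm)

T1  <- buildBrwMatrix(chainSpec())     # 16-state benchmark walk
pi0 <- analyticSteadyState(T1)         # exact stationary distribution
boundaryRate(pi0)                      # 7.743526e-09  (events per step)

tree <- runSimulation(T1, "lenient", nWalkers = 48, nCycles = 6000, seed = 1)
tree
#> TrajectoryTree: 6000 cycles x 48 walkers, tauWE = 1
#>   5999 merge (squash) events; resampler: lenient

pWE <- weStateProbabilities(tree)      # direct WE estimate
rmsle(pWE, pi0)
#> [1] 0.5950515

# lag-1 MSM and a merging-bias-corrected MSM at lag 75
C1 <- countsObserved(slidingWindows(tree, 1), 16, "w2")
m1 <- msmFromCounts(C1)
rmsle(stationaryDist(m1), pi0)
#> [1] 0.5927142

C75  <- countsObserved(slidingWindows(tree, 75), 16, "w2")
mbc  <- msmFromCounts(
  mbcCounts(C75, oneStepMatrix(tree), collectIncomplete(tree, 75)),
  kind = "mbc")
rmsle(stationaryDist(mbc), pi0)
#> [1] 0.5695902
```

`rmsle()` is the root-mean-square log10 error across all 16 states, in
orders of magnitude. Single runs scatter widely — this seed is on the
poor side of the distribution; across 10 replicate runs the cross-run
mean RMSLE is about 0.32 — and the corrected lag-75 model tracks the
lag-1 estimate closely on this chain (the methods vignette explains
why). The squashed-lineage bookkeeping itself is exact: column sums of
the corrected counts equal the observed sums plus the squashed weight
per start state to 1e-12.

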