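#' Trajectory-tree accessors
#'
#' Accessor generics for [TrajectoryTree-class] and the matrix containers.
#' Slots should never be reached into directly; these accessors are the
#' stable surface.
#'
#' @param x a `TrajectoryTree` (or, for `nStates`, any matrix-backed model
#'   object).
#' @return `nCycles`/`nWalkers` return single integers; the matrix accessors
#'   return the `[cycle, walker]` matrices described in
#'   [TrajectoryTree-class]; `treeSquashes` returns a data.frame.
#' @name tree-accessors
NULL

#' @rdname tree-accessors
#' @export
setGeneric("nCycles", function(x) standardGeneric("nCycles"))
#' @rdname tree-accessors
#' @export
setGeneric("nWalkers", function(x) standardGeneric("nWalkers"))
#' @rdname tree-accessors
#' @export
setGeneric("treeStates", function(x) standardGeneric("treeStates"))
#' @rdname tree-accessors
#' @export
setGeneric("treeWeights", function(x) standardGeneric("treeWeights"))
#' @rdname tree-accessors
#' @export
setGeneric("treeParents", function(x) standardGeneric("treeParents"))
#' @rdname tree-accessors
#' @export
setGeneric("treeCloneFrac", function(x) standardGeneric("treeCloneFrac"))
#' @rdname tree-accessors
#' @export
setGeneric("treeSquashes", function(x) standardGeneric("treeSquashes"))
#' @rdname tree-accessors
#' @export
setGeneric("treeFates", function(x) standardGeneric("treeFates"))
#' @rdname tree-accessors
#' @export
setGeneric("tauWE", function(x) standardGeneric("tauWE"))

#' @rdname tree-accessors
#' @export
setGeneric("nStates", function(x) standardGeneric("nStates"))

#' Extract the numeric matrix of a model object
#'
#' @param x a [TransitionMatrix-class] or [CountsMatrix-class].
#' @return the underlying numeric matrix (`[destination, origin]`).
#' @export
setGeneric("probMatrix", function(x) standardGeneric("probMatrix"))

#' @rdname probMatrix
#' @export
setGeneric("countMatrix", function(x) standardGeneric("countMatrix"))

#' Lag of a model object, in resampling intervals
#'
#' @param x a [TransitionMatrix-class], [CountsMatrix-class],
#'   [IncompleteEventSet-class] or [MsmModel-class].
#' @return a single integer.
#' @export
setGeneric("modelLag", function(x) standardGeneric("modelLag"))

#' Stationary distribution of an estimated model
#'
#' @param x an [MsmModel-class].
#' @return numeric probability vector over states.
#' @export
setGeneric("stationaryDist", function(x) standardGeneric("stationaryDist"))

setMethod("nCycles", "TrajectoryTree", function(x) nrow(x@states))
setMethod("nWalkers", "TrajectoryTree", function(x) ncol(x@states))
setMethod("treeStates", "TrajectoryTree", function(x) x@states)
setMethod("treeWeights", "TrajectoryTree", function(x) x@weights)
setMethod("treeParents", "TrajectoryTree", function(x) x@parents)
setMethod("treeCloneFrac", "TrajectoryTree", function(x) x@cloneFrac)
setMethod("treeSquashes", "TrajectoryTree", function(x) x@squashes)
setMethod("treeFates", "TrajectoryTree", function(x) x@fates)
setMethod("tauWE", "TrajectoryTree", function(x) x@tauWE)

setMethod("nStates", "ChainSpec", function(x) x@nStates)
setMethod("nStates", "TransitionMatrix", function(x) nrow(x@probs))
setMethod("nStates", "CountsMatrix", function(x) nrow(x@counts))
setMethod("nStates", "MsmModel", function(x) nrow(x@transition@probs))

setMethod("probMatrix", "TransitionMatrix", function(x) x@probs)
setMethod("countMatrix", "CountsMatrix", function(x) x@counts)

setMethod("modelLag", "TransitionMatrix", function(x) x@lag)
setMethod("modelLag", "CountsMatrix", function(x) x@lag@nTau)
setMethod("modelLag", "IncompleteEventSet", function(x) x@lag@nTau)
setMethod("modelLag", "MsmModel", function(x) x@transition@lag)

setMethod("stationaryDist", "MsmModel", function(x) x@pi)

setMethod("show", "ChainSpec", function(object) {
  cat(sprintf(
    "ChainSpec: %d states, pFwd = %g, pBwd = %g, warp = %s\n",
    object@nStates, object@pFwd, object@pBwd, object@warp))
})

setMethod("show", "TransitionMatrix", function(object) {
  cat(sprintf("TransitionMatrix: %d states, lag %d (column-stochastic, [to, from])\n",
              nrow(object@probs), object@lag))
})

setMethod("show", "TrajectoryTree", function(object) {
  cat(sprintf(
    "TrajectoryTree: %d cycles x %d walkers, tauWE = %g\n",
    nCycles(object), nWalkers(object), object@tauWE))
  cat(sprintf("  %d merge (squash) events; resampler: %s\n",
              nrow(object@squashes),
              if (!is.null(object@meta$resampler)) object@meta$resampler
              else "unknown"))
})

setMethod("show", "CountsMatrix", function(object) {
  cat(sprintf("CountsMatrix: %d states, lag %d, mode '%s', total weight %.6g\n",
              nrow(object@counts), object@lag@nTau, object@mode,
              sum(object@counts)))
})

setMethod("show", "IncompleteEventSet", function(object) {
  cat(sprintf(
    "IncompleteEventSet: M_1..M_%d over %d states, mode '%s', total %.6g\n",
    length(object@M), nrow(object@M[[1]]), object@mode,
    sum(vapply(object@M, sum, numeric(1)))))
})

setMethod("show", "MsmModel", function(object) {
  cat(sprintf("MsmModel (%s, %s counts): %d states, lag %d\n",
              object@provenance$kind %||% "?",
              object@provenance$mode %||% "?",
              nStates(object), modelLag(object)))
})

setMethod("show", "RevoParams", function(object) {
  cat(sprintf(
    "RevoParams: d0 = %g, alpha = %g, pMin = %g, pMax = %g, C = %g\n",
    object@d0, object@alpha, object@pMin, object@pMax, object@C))
  cat(sprintf("  merge: %s (mergeDist = %g), epsilon = %g\n",
              object@mergeMode, object@mergeDist, object@epsilon))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
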