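#' Serialize a trajectory tree to JSON
#'
#' Writes all tree components — per-cycle states, weights, parents, clone
#' fractions, squash records, fates and metadata — to a single JSON file at
#' full double precision, so [readTree()] reproduces the object exactly.
#'
#' @param tree a [TrajectoryTree-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeTree <- function(tree, path) {
  stopifnot(is(tree, "TrajectoryTree"))
  payload <- list(
    format = "mbcmsm-tree", version = 1L,
    nCycles = nCycles(tree), nWalkers = nWalkers(tree),
    tauWE = tree@tauWE,
    states = tree@states, weights = tree@weights,
    parents = tree@parents, cloneFrac = tree@cloneFrac,
    squashes = tree@squashes, fates = tree@fates,
    meta = tree@meta)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname writeTree
#' @export
readTree <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "mbcmsm-tree"))
    stop("not an mbcmsm tree file: ", path)
  sq <- as.data.frame(p$squashes)
  if (nrow(sq) == 0L)
    sq <- data.frame(cycle = integer(), walker = integer(),
                     frac = numeric(), into = integer())
  meta <- p$meta
  if (is.null(meta)) meta <- list()
  st <- p$states; storage.mode(st) <- "integer"
  pa <- p$parents; storage.mode(pa) <- "integer"
  # JSON writes integral doubles without a decimal point; restore types
  wt <- p$weights; storage.mode(wt) <- "double"
  fr <- p$cloneFrac; storage.mode(fr) <- "double"
  sq$frac <- as.double(sq$frac)
  sq$cycle <- as.integer(sq$cycle)
  sq$walker <- as.integer(sq$walker)
  sq$into <- as.integer(sq$into)
  new("TrajectoryTree", states = st, weights = wt, parents = pa,
      cloneFrac = fr, squashes = sq, fates = p$fates,
      tauWE = as.double(p$tauWE), meta = as.list(meta))
}

#' Write transition events or incomplete-event matrices as TSV
#'
#' `writeEventsTsv` writes the event table of [slidingWindows()] unchanged;
#' `writeIncompleteTsv` writes the M_i matrices in long format with columns
#' `i` (steps remaining), `j` (0-based start state), `k` (squash state) and
#' `weight`, omitting zero entries. Numeric columns are printed with 17
#' significant digits so reading the file back reproduces the doubles
#' exactly.
#'
#' @param events data.frame from [slidingWindows()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeEventsTsv <- function(events, path) {
  writeSummaryTsv(events, path)
}

#' @rdname writeEventsTsv
#' @param M an [IncompleteEventSet-class].
#' @export
writeIncompleteTsv <- function(M, path) {
  rows <- lapply(seq_along(M@M), function(i) {
    m <- M@M[[i]]
    nz <- which(m != 0, arr.ind = TRUE)
    if (nrow(nz) == 0L) return(NULL)
    data.frame(i = i, j = nz[, 2L] - 1L, k = nz[, 1L] - 1L,
               weight = m[nz])
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(i = integer(), j = integer(), k = integer(),
                     weight = numeric())
  writeSummaryTsv(df, path)
}

#' Exact-round-trip TSV writer and reader for result tables
#'
#' Numeric columns are formatted with 17 significant digits (`%.17g`), the
#' shortest representation guaranteed to survive a parse round trip, so
#' `readSummaryTsv(writeSummaryTsv(df, p))` reproduces the in-memory values
#' exactly.
#'
#' @param df a data.frame of atomic columns.
#' @param path file path.
#' @return `writeSummaryTsv` returns `path` invisibly; `readSummaryTsv`
#'   returns a data.frame.
#' @export
writeSummaryTsv <- function(df, path) {
  out <- df
  for (nm in names(out)) {
    if (is.double(out[[nm]])) out[[nm]] <- sprintf("%.17g", out[[nm]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeSummaryTsv
#' @export
readSummaryTsv <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}
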