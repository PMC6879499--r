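#' Read a compound-by-protein docking-score matrix from CSV
#'
#' Expects a header row of protein ids and a first column of compound ids
#' (scores on the 0-10 pKd/pKi scale). Empty cells, "NA" and "NaN" are
#' missing values. Orientation can be forced with \code{transpose}, or
#' auto-detected against a reference set of compound ids.
#'
#' @param path CSV file.
#' @param transpose set TRUE when the file is proteins x compounds.
#' @param compoundRef optional character vector of known compound ids used
#'   to auto-detect orientation (rows win ties).
#' @return a \linkS4class{DockingScoreMatrix}.
#' @export
readDockingMatrix <- function(path, transpose = FALSE, compoundRef = NULL) {
  if (!file.exists(path)) stop("cannot read docking matrix: ", path)
  m <- .readLabelledCsv(path)
  storage.mode(m) <- "double"
  if (!is.null(compoundRef)) {
    rowHits <- mean(rownames(m) %in% compoundRef)
    colHits <- mean(colnames(m) %in% compoundRef)
    if (colHits > rowHits) transpose <- TRUE
  }
  if (transpose) m <- t(m)
  if (anyDuplicated(rownames(m)))
    stop("duplicate compound ids in docking matrix")
  if (anyDuplicated(colnames(m)))
    stop("duplicate protein ids in docking matrix")
  bad <- which(!is.na(m) & (m < 0 | m > 10), arr.ind = TRUE)
  if (nrow(bad))
    stop("docking score out of the 0-10 range at (",
         rownames(m)[bad[1, 1]], ", ", colnames(m)[bad[1, 2]], "): ",
         m[bad[1, , drop = FALSE]])
  new("DockingScoreMatrix", m)
}

#' Write a docking-score matrix (or rank/effect matrix) as labelled CSV
#' @param m a matrix-backed object with dimnames.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeDockingMatrix <- function(m, path) {
  .writeLabelledCsv(as(m, "matrix"), path)
  invisible(path)
}

#' @rdname rankNormalize
#' @aliases rankNormalize,DockingScoreMatrix-method
setMethod("rankNormalize", "DockingScoreMatrix", function(m) {
  scores <- m@.Data
  ranks <- scores
  for (i in seq_len(nrow(scores))) {
    row <- scores[i, ]
    present <- !is.na(row)
    if (sum(present) == 0)
      stop("all docking scores missing for compound ", rownames(scores)[i])
    if (sum(present) < 2)
      stop("need >= 2 scores to rank compound ", rownames(scores)[i])
    ## descending: rank 1 = highest score; ties -> average rank
    ranks[i, present] <- rank(-row[present], ties.method = "average")
  }
  new("RankMatrix", ranks)
})

#' @rdname compoundIds
#' @aliases compoundIds,DockingScoreMatrix-method
setMethod("compoundIds", "DockingScoreMatrix", function(x) rownames(x@.Data))
#' @rdname compoundIds
#' @aliases compoundIds,RankMatrix-method
setMethod("compoundIds", "RankMatrix", function(x) rownames(x@.Data))
#' @rdname compoundIds
#' @aliases compoundIds,NetworkEffectMatrix-method
setMethod("compoundIds", "NetworkEffectMatrix",
          function(x) rownames(x@.Data))

#' @rdname proteinIds
#' @aliases proteinIds,DockingScoreMatrix-method
setMethod("proteinIds", "DockingScoreMatrix", function(x) colnames(x@.Data))
#' @rdname proteinIds
#' @aliases proteinIds,RankMatrix-method
setMethod("proteinIds", "RankMatrix", function(x) colnames(x@.Data))
#' @rdname proteinIds
#' @aliases proteinIds,NetworkEffectMatrix-method
setMethod("proteinIds", "NetworkEffectMatrix", function(x) colnames(x@.Data))

setMethod("show", "DockingScoreMatrix", function(object) {
  cat("DockingScoreMatrix:", nrow(object), "compounds x", ncol(object),
      "proteins;", sum(is.na(object@.Data)), "missing\n")
})
setMethod("show", "RankMatrix", function(object) {
  cat("RankMatrix:", nrow(object), "compounds x", ncol(object),
      "proteins (1 = strongest docking score)\n")
})
setMethod("show", "NetworkEffectMatrix", function(object) {
  cat("NetworkEffectMatrix:", nrow(object), "compounds x", ncol(object),
      "proteins (rank x PPI degree)\n")
})
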