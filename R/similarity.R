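#' @rdname similarityMatrix
#' @aliases similarityMatrix,CompoundSet-method
setMethod("similarityMatrix", "CompoundSet",
  function(set, method = c("mcs_overlap", "morgan_tanimoto"), ...) {
    method <- match.arg(method)
    n <- nCompounds(set)
    if (n < 2) stop("need at least 2 compounds for a similarity matrix")
    dots <- list(...)
    m <- diag(1, n)
    dimnames(m) <- list(set@ids, set@ids)
    if (method == "mcs_overlap") {
      params <- if (!is.null(dots$params)) dots$params else mcsParams()
      for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
        r <- tryCatch(mcsOverlap(set@graphs[[i]], set@graphs[[j]], params),
                      error = function(e)
                        stop("similarity failed for pair (", set@ids[i],
                             ", ", set@ids[j], "): ", conditionMessage(e)))
        if (r@timedOut)
          warning("MCS timed out for pair (", set@ids[i], ", ", set@ids[j],
                  "); using best size found", call. = FALSE)
        m[i, j] <- m[j, i] <- r@coefficient
      }
    } else {
      radius <- if (!is.null(dots$radius)) dots$radius else 2L
      nBits <- if (!is.null(dots$nBits)) dots$nBits else 2048L
      fps <- lapply(set@graphs, morganFingerprint, radius = radius,
                    nBits = nBits)
      for (i in seq_len(n - 1)) for (j in seq((i + 1), n))
        m[i, j] <- m[j, i] <- tanimotoCoefficient(fps[[i]], fps[[j]])
    }
    new("SimilarityMatrix", m, method = method)
  })

setMethod("show", "SimilarityMatrix", function(object) {
  cat("SimilarityMatrix (", object@method, ") over ", nrow(object),
      " compounds\n", sep = "")
  print(round(object@.Data, 3))
})

#' @rdname compoundIds
#' @aliases compoundIds,SimilarityMatrix-method
setMethod("compoundIds", "SimilarityMatrix", function(x) rownames(x@.Data))

#' Write a labelled square similarity matrix as CSV
#'
#' Full square matrix with compound ids as both row and column headers;
#' values at full precision so a read round-trips bit-exactly.
#'
#' @param m a \linkS4class{SimilarityMatrix} (or any labelled matrix).
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeSimilarityCsv <- function(m, path) {
  .writeLabelledCsv(as(m, "matrix"), path)
  invisible(path)
}

#' Read a labelled square similarity matrix from CSV
#' @param path CSV written by \code{\link{writeSimilarityCsv}}.
#' @param method similarity method tag to attach.
#' @return a \linkS4class{SimilarityMatrix}.
#' @export
readSimilarityCsv <- function(path, method = "mcs_overlap") {
  m <- .readLabelledCsv(path)
  new("SimilarityMatrix", m, method = method)
}

## shared labelled-CSV helpers (full precision; RFC-4180 via read/write.csv)
.writeLabelledCsv <- function(m, path) {
  df <- data.frame(id = rownames(m),
                   format(m, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE)
  names(df)[1] <- ""
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
}

.readLabelledCsv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, row.names = 1,
                        na.strings = c("", "NA", "NaN"))
  as.matrix(df)
}
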