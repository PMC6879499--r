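#' Load compounds from SDF, MOL or SMILES files
#'
#' Parses a structure file into a \linkS4class{CompoundSet}, one record per
#' parseable molecule in file order. Compound ids come from the SDF title
#' line or the second column of a SMILES line; records without an id get
#' \code{"cpd_<index>"}. Explicit hydrogens are stripped and kekulized
#' aromatic rings re-perceived, so similarity is computed over heavy atoms.
#'
#' SMILES files carry one molecule per line as \code{"SMILES[ \t]id"};
#' blank lines and lines starting with \code{#} are ignored.
#'
#' @param path path to the structure file.
#' @param format \code{"auto"} (default; resolved from the file
#'   extension), \code{"sdf"}, \code{"mol"} or \code{"smiles"}.
#' @param strict when TRUE an unparseable entry aborts the load instead of
#'   being skipped with a warning.
#' @return a \linkS4class{CompoundSet}.
#' @examples
#' f <- tempfile(fileext = ".smi")
#' writeLines(c("CCO ethanol", "CC(=O)O acetic_acid"), f)
#' cs <- loadCompounds(f)
#' compoundIds(cs)
#' @export
loadCompounds <- function(path, format = c("auto", "sdf", "mol", "smiles"),
                          strict = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read compound file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      sdf = "sdf", mol = "mol", smi = "smiles", smiles = "smiles",
      txt = "smiles",
      stop("cannot resolve format from extension '", ext,
           "'; pass format= explicitly"))
  }
  if (format == "smiles") .loadSmilesFile(path, strict)
  else .loadSdfFile(path, format, strict)
}

#' Build a CompoundSet directly from SMILES strings
#'
#' @param smiles character vector of SMILES.
#' @param ids compound ids (default from names, else cpd_<i>).
#' @param strict abort on an unparseable SMILES instead of skipping.
#' @return a \linkS4class{CompoundSet}.
#' @export
compoundsFromSmiles <- function(smiles, ids = NULL, strict = FALSE) {
  if (is.null(ids)) ids <- names(smiles)
  if (is.null(ids)) ids <- paste0("cpd_", seq_along(smiles))
  .buildSet(smiles, ids, "smiles", strict)
}

.loadSmilesFile <- function(path, strict) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("empty input: no molecules in ", path)
  parts <- strsplit(lines, "[ \t]+")
  smiles <- vapply(parts, `[`, character(1), 1)
  ids <- vapply(seq_along(parts), function(i) {
    if (length(parts[[i]]) >= 2) parts[[i]][2] else paste0("cpd_", i)
  }, character(1))
  .buildSet(smiles, ids, "smiles", strict)
}

.buildSet <- function(smiles, ids, sourceFormat, strict) {
  graphs <- vector("list", length(smiles))
  canon <- character(length(smiles))
  ok <- logical(length(smiles))
  for (i in seq_along(smiles)) {
    res <- tryCatch({
      sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles[i]))
      g <- .graphFromSDF(sdf[[1]])
      cn <- as.character(ChemmineR::sdf2smiles(sdf))
      list(g = g, canon = cn)
    }, error = function(e) e)
    if (inherits(res, "error"))
      res <- tryCatch(.parseSmilesDirect(smiles[i]), error = function(e) res)
    if (inherits(res, "error")) {
      msg <- paste0("could not parse molecule '", ids[i], "': ",
                    conditionMessage(res))
      if (strict) stop(msg)
      warning(msg, call. = FALSE)
    } else {
      graphs[[i]] <- res$g
      canon[i] <- res$canon
      ok[i] <- TRUE
    }
  }
  if (!any(ok)) stop("empty input: no parseable molecules")
  new("CompoundSet", ids = ids[ok], compoundNames = ids[ok],
      smiles = canon[ok], graphs = graphs[ok], sourceFormat = sourceFormat)
}

## fallback parse for molecules the SDF container class rejects
.parseSmilesDirect <- function(smi) {
  mb <- ChemmineOB::convertFormat("SMI", "MOL", paste0(smi, "\n"))
  if (!nzchar(trimws(mb))) stop("unparseable SMILES")
  g <- .graphFromMolblock(mb)
  cn <- trimws(sub("[ \t].*$", "",
                   ChemmineOB::convertFormat("SMI", "CAN",
                                             paste0(smi, "\n"))))
  if (!nzchar(cn)) stop("unparseable SMILES")
  list(g = g, canon = cn)
}

.parseMolblockDirect <- function(recordText) {
  g <- .graphFromMolblock(recordText)
  cn <- trimws(sub("[ \t].*$", "",
                   ChemmineOB::convertFormat("MOL", "CAN", recordText)))
  if (!nzchar(cn)) stop("unparseable molblock")
  list(g = g, canon = cn)
}

.loadSdfFile <- function(path, format, strict) {
  txt <- readLines(path, warn = FALSE)
  if (!length(txt) || all(!nzchar(trimws(txt))))
    stop("empty input: no molecules in ", path)
  if (format == "mol" && !any(grepl("^\\${4}", txt))) txt <- c(txt, "$$$$")
  ## raw record texts, for the bond-less fallback path
  recEnds <- grep("^\\$\\$\\$\\$", txt)
  recStarts <- c(1L, utils::head(recEnds, -1) + 1L)
  records <- mapply(function(s, e) paste(txt[s:(e - 1)], collapse = "\n"),
                    recStarts, recEnds)
  tmp <- tempfile(fileext = ".sdf")
  on.exit(unlink(tmp))
  writeLines(txt, tmp)
  sdfset <- tryCatch(ChemmineR::read.SDFset(tmp, skipErrors = TRUE),
                     error = function(e)
                       stop("unreadable SDF file: ", conditionMessage(e)))
  n <- length(sdfset)
  if (n == 0) stop("empty input: no parseable molecules")
  ids <- character(n); graphs <- vector("list", n); canon <- character(n)
  ok <- logical(n)
  titles <- ChemmineR::sdfid(sdfset)
  for (i in seq_len(n)) {
    ids[i] <- if (!is.na(titles[i]) && nzchar(trimws(titles[i])))
      trimws(titles[i]) else paste0("cpd_", i)
    res <- tryCatch({
      g <- .graphFromSDF(sdfset[[i]])
      cn <- as.character(ChemmineR::sdf2smiles(sdfset[i]))
      list(g = g, canon = cn)
    }, error = function(e) e)
    if (inherits(res, "error") && i <= length(records))
      res <- tryCatch(.parseMolblockDirect(records[i]),
                      error = function(e) res)
    if (inherits(res, "error")) {
      msg <- paste0("could not parse molecule '", ids[i], "': ",
                    conditionMessage(res))
      if (strict) stop(msg)
      warning(msg, call. = FALSE)
    } else {
      graphs[[i]] <- res$g; canon[i] <- res$canon; ok[i] <- TRUE
    }
  }
  if (!any(ok)) stop("empty input: no parseable molecules")
  ids <- make.unique(ids[ok])
  new("CompoundSet", ids = ids, compoundNames = ids, smiles = canon[ok],
      graphs = graphs[ok], sourceFormat = format)
}

#' @rdname compoundIds
#' @aliases compoundIds,CompoundSet-method
setMethod("compoundIds", "CompoundSet", function(x) x@ids)

#' @rdname nCompounds
#' @aliases nCompounds,CompoundSet-method
setMethod("nCompounds", "CompoundSet", function(x) length(x@ids))

setMethod("show", "CompoundSet", function(object) {
  cat("CompoundSet of", length(object@ids), "compounds (",
      object@sourceFormat, ")\n")
  heavy <- vapply(object@graphs, heavyAtomCount, integer(1))
  n <- min(6L, length(object@ids))
  for (i in seq_len(n))
    cat(sprintf("  %-16s %3d heavy atoms  %s\n", object@ids[i], heavy[i],
                substr(object@smiles[i], 1, 40)))
  if (length(object@ids) > n) cat("  ...\n")
})

#' Subset a CompoundSet
#' @param x CompoundSet
#' @param i index vector (integer, logical or compound ids)
#' @param j,drop,... ignored
#' @export
setMethod("[", "CompoundSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@ids)
  new("CompoundSet", ids = x@ids[i], compoundNames = x@compoundNames[i],
      smiles = x@smiles[i], graphs = x@graphs[i],
      sourceFormat = x@sourceFormat)
})

#' Molecular graph of one compound
#' @param set a CompoundSet.
#' @param id compound id or index.
#' @return the molecular graph list.
#' @export
compoundGraph <- function(set, id) {
  i <- if (is.character(id)) match(id, set@ids) else id
  if (is.na(i)) stop("unknown compound: ", id)
  set@graphs[[i]]
}
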