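#' Read a protein-protein interaction network from an edge-list export
#'
#' Supported formats: \code{string_tsv} — a STRING database export with
#' columns \code{protein1 protein2 combined_score} (whitespace- or
#' tab-separated; combined scores on the 0-1000 integer scale are divided
#' by 1000 on read, so \code{minConfidence = 0.7} corresponds to STRING's
#' "high confidence" 700); \code{sif} — simple interaction format
#' \code{A relation B [C D ...]}; \code{tsv2col} — two tab/space-separated
#' columns, optional third numeric confidence in [0, 1].
#'
#' Edges below \code{minConfidence} are dropped (formats without a
#' confidence keep all edges); self-loops and duplicate edges are removed
#' with a logged count. The node set is the endpoints of surviving edges,
#' plus any isolated proteins listed in \code{nodeFile} (one id per line).
#'
#' @param path edge-list file.
#' @param format one of \code{"string_tsv"}, \code{"sif"}, \code{"tsv2col"}.
#' @param minConfidence minimum interaction confidence kept (default 0.7).
#' @param nodeFile optional file of node ids to retain even when isolated.
#' @param strict abort on malformed lines instead of skipping them.
#' @return an undirected \pkg{igraph} graph; kept confidences are stored
#'   in the \code{confidence} edge attribute when available.
#' @export
readPPI <- function(path, format = c("string_tsv", "sif", "tsv2col"),
                    minConfidence = 0.7, nodeFile = NULL, strict = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read PPI file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  edges <- list(); conf <- numeric(0)
  badLine <- function(i, why) {
    msg <- paste0("malformed PPI line ", i, " (", why, "); skipped")
    if (strict) stop(msg) else warning(msg, call. = FALSE)
  }
  if (format == "string_tsv") {
    if (!length(lines)) stop("empty PPI file")
    header <- strsplit(lines[1], "[ \t]+")[[1]]
    need <- c("protein1", "protein2", "combined_score")
    if (!all(need %in% header))
      stop("string_tsv requires columns protein1, protein2, combined_score")
    ix <- match(need, header)
    for (i in seq_along(lines)[-1]) {
      f <- strsplit(lines[i], "[ \t]+")[[1]]
      if (length(f) < max(ix)) { badLine(i, "too few fields"); next }
      s <- suppressWarnings(as.numeric(f[ix[3]]))
      if (is.na(s)) { badLine(i, "non-numeric combined_score"); next }
      edges[[length(edges) + 1L]] <- c(f[ix[1]], f[ix[2]])
      conf <- c(conf, s / 1000)
    }
  } else if (format == "sif") {
    for (i in seq_along(lines)) {
      f <- strsplit(lines[i], "[ \t]+")[[1]]
      if (length(f) == 1) { edges[[length(edges) + 1L]] <- c(f[1], NA); next }
      if (length(f) < 3) { badLine(i, "expected 'A relation B'"); next }
      for (tgt in f[-(1:2)]) {
        edges[[length(edges) + 1L]] <- c(f[1], tgt)
        conf <- c(conf, NA_real_)
      }
    }
  } else {
    for (i in seq_along(lines)) {
      f <- strsplit(lines[i], "[ \t]+")[[1]]
      if (length(f) < 2) { badLine(i, "expected two columns"); next }
      edges[[length(edges) + 1L]] <- c(f[1], f[2])
      conf <- c(conf, if (length(f) >= 3)
        suppressWarnings(as.numeric(f[3])) else NA_real_)
    }
  }
  singles <- vapply(edges, function(e) is.na(e[2]), logical(1))
  loneNodes <- vapply(edges[singles], `[`, character(1), 1)
  edges <- edges[!singles]
  if (length(conf) == length(singles)) conf <- conf[!singles]
  el <- if (length(edges)) do.call(rbind, edges) else
    matrix(character(0), ncol = 2)
  keep <- rep(TRUE, nrow(el))
  hasConf <- length(conf) == nrow(el) && any(!is.na(conf))
  if (hasConf) {
    if (any(conf < 0 | conf > 1, na.rm = TRUE))
      stop("confidence values must lie in [0, 1] after scaling")
    keep <- is.na(conf) | conf >= minConfidence
    message(sum(!keep), " edges below confidence ", minConfidence,
            " dropped")
  }
  el <- el[keep, , drop = FALSE]
  conf <- if (hasConf) conf[keep] else rep(NA_real_, nrow(el))
  ## self-loops and duplicates (either orientation)
  self <- el[, 1] == el[, 2]
  if (any(self)) message(sum(self), " self-loops removed")
  key <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  dup <- duplicated(key) & !self
  if (any(dup)) message(sum(dup), " duplicate edges removed")
  keepRetained <- unique(c(el[self, 1], loneNodes))
  el2 <- el[!self & !dup, , drop = FALSE]
  conf2 <- conf[!self & !dup]
  g <- igraph::graph_from_edgelist(el2, directed = FALSE)
  if (nrow(el2)) igraph::E(g)$confidence <- conf2
  extra <- setdiff(keepRetained, igraph::V(g)$name)
  if (length(extra)) g <- igraph::add_vertices(g, length(extra), name = extra)
  if (!is.null(nodeFile)) {
    ids <- trimws(readLines(nodeFile, warn = FALSE))
    ids <- ids[nzchar(ids) & !startsWith(ids, "#")]
    extra <- setdiff(ids, igraph::V(g)$name)
    if (length(extra))
      g <- igraph::add_vertices(g, length(extra), name = extra)
  }
  g
}

#' Node degrees of a PPI network
#'
#' The degree of a protein — the number of interactions it makes — is the
#' topology weight used by the network-effect score; hub proteins carry
#' the system-level impact of binding.
#'
#' @param g an undirected igraph (see \code{\link{readPPI}}).
#' @return named integer vector, one entry per node (0 for isolated
#'   nodes); empty graph gives an empty vector.
#' @export
nodeDegrees <- function(g) {
  d <- igraph::degree(g, loops = FALSE)
  storage.mode(d) <- "integer"
  d
}

#' Betweenness centrality of a PPI network (report-only)
#'
#' Computed for network topology reports and plots; it does not enter the
#' network-effect score.
#'
#' @param g an undirected igraph.
#' @return named numeric vector of betweenness values.
#' @export
nodeBetweenness <- function(g) igraph::betweenness(g, directed = FALSE)

#' @rdname networkEffect
#' @aliases networkEffect,RankMatrix,numeric-method
setMethod("networkEffect", signature(ranks = "RankMatrix",
                                     degrees = "numeric"),
  function(ranks, degrees, missingPolicy = c("zero", "drop", "error")) {
    missingPolicy <- match.arg(missingPolicy)
    if (is.null(names(degrees))) stop("degrees must be a named vector")
    r <- ranks@.Data
    prots <- colnames(r)
    absent <- setdiff(prots, names(degrees))
    if (length(absent) == length(prots))
      stop("no rank proteins found in the degree table")
    if (length(absent)) {
      message(length(absent), " rank proteins absent from degree table (",
              paste(utils::head(absent, 5), collapse = ", "),
              if (length(absent) > 5) ", ..." else "", "); policy = ",
              missingPolicy)
      if (missingPolicy == "error")
        stop("proteins missing from degree table: ",
             paste(absent, collapse = ", "))
      if (missingPolicy == "drop")
        r <- r[, setdiff(prots, absent), drop = FALSE]
    }
    deg <- degrees[colnames(r)]
    deg[is.na(deg)] <- 0          # zero policy
    eff <- sweep(r, 2, deg, `*`)
    new("NetworkEffectMatrix", eff)
  })

#' Write a degree table as CSV
#' @param degrees named vector from \code{\link{nodeDegrees}}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeDegreeTable <- function(degrees, path) {
  utils::write.csv(data.frame(protein = names(degrees),
                              degree = as.integer(degrees)),
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Write a graph as SIF
#' @param g an undirected igraph.
#' @param path output file.
#' @param relation relation label (default "pp").
#' @return invisibly, the path.
#' @export
writeSif <- function(g, path, relation = "pp") {
  el <- igraph::as_edgelist(g)
  lines <- if (nrow(el)) paste(el[, 1], relation, el[, 2]) else character(0)
  iso <- igraph::V(g)$name[igraph::degree(g) == 0]
  writeLines(c(lines, iso), path)
  invisible(path)
}
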