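#' Configuration for a three-axis deep screen
#'
#' Bundles all paths and parameters of \code{\link{runPipeline}} into a
#' validated list. A YAML document with the same keys can be loaded with
#' \code{\link{readScreenConfig}}; the config is echoed verbatim into the
#' run report for provenance.
#'
#' @param compounds path to the compound structure file (SDF/MOL/SMILES).
#' @param docking path to the compound x protein docking-score CSV.
#' @param ppi path to the PPI edge-list file.
#' @param outDir output directory (created on run).
#' @param seed integer RNG seed; mandatory (bootstrap reproducibility).
#' @param similarityMethod "mcs_overlap" or "morgan_tanimoto".
#' @param mcsTimeout per-pair MCS time budget in seconds.
#' @param radius,nBits Morgan fingerprint parameters.
#' @param ppiFormat "string_tsv", "sif" or "tsv2col".
#' @param minConfidence minimum PPI confidence kept (default 0.7).
#' @param linkage clustering linkage (default "average").
#' @param scales multiscale-bootstrap scales.
#' @param nboot bootstrap replicates per scale.
#' @param missingProteinPolicy see \code{\link{networkEffect}}.
#' @param compareK integer vector of flat-cut sizes for tree comparison.
#' @param idMap optional two-column TSV (from, to) aliasing docking
#'   compound ids to structure-file ids.
#' @param strict abort on any parse warning.
#' @param plots write PNG dendrograms (default TRUE).
#' @return a list of class \code{screenConfig}.
#' @export
screenConfig <- function(compounds, docking, ppi, outDir, seed,
                         similarityMethod = c("mcs_overlap",
                                              "morgan_tanimoto"),
                         mcsTimeout = 10, radius = 2L, nBits = 2048L,
                         ppiFormat = c("string_tsv", "sif", "tsv2col"),
                         minConfidence = 0.7, linkage = "average",
                         scales = seq(0.5, 1.4, by = 0.1), nboot = 1000,
                         missingProteinPolicy = c("zero", "drop", "error"),
                         compareK = 2:4, idMap = NULL, strict = FALSE,
                         plots = TRUE) {
  cfg <- list(compounds = compounds, docking = docking, ppi = ppi,
              outDir = outDir, seed = as.integer(seed),
              similarityMethod = match.arg(similarityMethod),
              mcsTimeout = mcsTimeout, radius = radius, nBits = nBits,
              ppiFormat = match.arg(ppiFormat),
              minConfidence = minConfidence, linkage = linkage,
              scales = scales, nboot = as.integer(nboot),
              missingProteinPolicy = match.arg(missingProteinPolicy),
              compareK = as.integer(compareK), idMap = idMap,
              strict = isTRUE(strict), plots = isTRUE(plots))
  class(cfg) <- "screenConfig"
  cfg
}

#' Load a screen configuration from a YAML file
#' @param path YAML file with \code{\link{screenConfig}} keys.
#' @param ... overrides applied on top of the file values.
#' @return a \code{screenConfig} list.
#' @export
readScreenConfig <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  over <- list(...)
  vals[names(over)] <- over
  do.call(screenConfig, vals)
}

.validateConfig <- function(cfg) {
  if (!inherits(cfg, "screenConfig")) stop("not a screenConfig")
  for (key in c("compounds", "docking", "ppi")) {
    p <- cfg[[key]]
    if (is.null(p) || !nzchar(p))
      stop("config is missing the '", key, "' input path")
    if (!file.exists(p)) stop("config input does not exist: ", key,
                              " = ", p)
  }
  if (is.na(cfg$seed)) stop("config seed is mandatory")
  invisible(cfg)
}

## restrict a feature matrix to complete (no-NA) columns, with a log line
.completeColumns <- function(m, what) {
  bad <- colSums(is.na(m)) > 0
  if (any(bad))
    message(sum(bad), " ", what,
            " columns with missing values excluded from clustering")
  m[, !bad, drop = FALSE]
}

#' Run the full three-axis deep-screen pipeline
#'
#' Executes, in order: load compounds; structural similarity matrix and
#' structure-axis clustering; docking-score matrix and docking-axis
#' clustering; rank normalization; PPI network, node degrees and
#' network-effect matrix; network-axis clustering; pairwise dendrogram
#' comparison at each configured k. Every clustering is a multiscale
#' bootstrap over the matching feature columns (similarity profiles,
#' docking scores, network effects) with AU support values. All matrices,
#' Newick dendrograms, support tables, the comparison table and a JSON
#' report are written under \code{outDir}; outputs are byte-identical
#' across reruns with the same config and seed.
#'
#' @param config a \code{\link{screenConfig}}.
#' @return a \linkS4class{ScreenReport}.
#' @export
runPipeline <- function(config) {
  .validateConfig(config)
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outDir, f)
  warningsSeen <- character(0)
  withCallingHandlers({
    set <- loadCompounds(config$compounds, strict = config$strict)

    ## --- structure axis ---
    sim <- if (config$similarityMethod == "mcs_overlap")
      similarityMatrix(set, "mcs_overlap",
                       params = mcsParams(timeout = config$mcsTimeout))
    else similarityMatrix(set, "morgan_tanimoto", radius = config$radius,
                          nBits = config$nBits)
    writeSimilarityCsv(sim, out("similarity.csv"))
    structCl <- multiscaleBootstrap(as(sim, "matrix"),
                                    linkage = config$linkage,
                                    scales = config$scales,
                                    nboot = config$nboot,
                                    seed = config$seed, axis = "structure")

    ## --- docking axis ---
    dock <- readDockingMatrix(config$docking,
                              compoundRef = compoundIds(set))
    if (!is.null(config$idMap)) {
      map <- utils::read.delim(config$idMap, header = TRUE,
                               stringsAsFactors = FALSE)
      hit <- match(rownames(dock@.Data), map[[1]])
      rn <- rownames(dock@.Data)
      rn[!is.na(hit)] <- map[[2]][hit[!is.na(hit)]]
      rownames(dock@.Data) <- rn
    }
    misA <- setdiff(compoundIds(set), compoundIds(dock))
    misB <- setdiff(compoundIds(dock), compoundIds(set))
    if (length(misA) || length(misB))
      stop("compound ids differ between structure file and docking ",
           "matrix; symmetric difference: ",
           paste(c(misA, misB), collapse = ", "))
    dockM <- dock@.Data[compoundIds(set), , drop = FALSE]
    dockCl <- multiscaleBootstrap(.completeColumns(dockM, "docking"),
                                  linkage = config$linkage,
                                  scales = config$scales,
                                  nboot = config$nboot,
                                  seed = config$seed + 1L,
                                  axis = "docking")

    ## --- network axis ---
    ranks <- rankNormalize(new("DockingScoreMatrix", dockM))
    writeDockingMatrix(ranks, out("ranks.csv"))
    g <- readPPI(config$ppi, format = config$ppiFormat,
                 minConfidence = config$minConfidence,
                 strict = config$strict)
    degrees <- nodeDegrees(g)
    writeDegreeTable(degrees, out("degrees.csv"))
    utils::write.csv(data.frame(protein = names(degrees),
                                betweenness = nodeBetweenness(g)),
                     out("betweenness.csv"), row.names = FALSE)
    writeSif(g, out("ppi_network.sif"))
    eff <- networkEffect(ranks, degrees,
                         missingPolicy = config$missingProteinPolicy)
    writeDockingMatrix(eff, out("network_effect.csv"))
    netCl <- multiscaleBootstrap(.completeColumns(eff@.Data, "effect"),
                                 linkage = config$linkage,
                                 scales = config$scales,
                                 nboot = config$nboot,
                                 seed = config$seed + 2L,
                                 axis = "network")

    ## --- outputs and comparison ---
    cls <- list(structure = structCl, docking = dockCl, network = netCl)
    for (axis in names(cls)) {
      writeNewick(cls[[axis]], out(paste0("dendrogram_", axis, ".nwk")))
      writeSupportTable(cls[[axis]], out(paste0("support_", axis, ".csv")))
      if (config$plots) {
        grDevices::png(out(paste0("dendrogram_", axis, ".png")),
                       width = 900, height = 600)
        tryCatch(plotSupport(cls[[axis]]),
                 finally = grDevices::dev.off())
      }
    }
    pairsAxes <- utils::combn(names(cls), 2)
    comp <- do.call(rbind, lapply(seq_len(ncol(pairsAxes)), function(p) {
      do.call(rbind, lapply(config$compareK, function(k) {
        rec <- compareTrees(cls[[pairsAxes[1, p]]], cls[[pairsAxes[2, p]]],
                            k = k)
        cbind(data.frame(axisA = pairsAxes[1, p],
                         axisB = pairsAxes[2, p]), rec)
      }))
    }))
    utils::write.csv(comp, out("comparisons.csv"), row.names = FALSE)

    meta <- list(package = "deepscreen",
                 version = as.character(utils::packageVersion("deepscreen")),
                 rVersion = R.version.string,
                 config = unclass(config),
                 clusterOrientation = paste(
                   "items = compounds; features = matrix columns;",
                   "bootstrap resamples feature columns"),
                 warnings = warningsSeen,
                 timestamp = format(Sys.time(), tz = "UTC",
                                    "%Y-%m-%dT%H:%M:%SZ"))
    report <- new("ScreenReport", clusterings = cls, comparisons = comp,
                  metadata = meta)
    jsonlite::write_json(
      list(metadata = meta, comparisons = comp,
           support = lapply(cls, function(x)
             supportTable(x)[, c("cluster", "members", "au", "bp")])),
      out("report.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
    report
  }, warning = function(w) {
    warningsSeen <<- c(warningsSeen, conditionMessage(w))
    if (config$strict) stop("strict mode: ", conditionMessage(w))
    invokeRestart("muffleWarning")
  })
}

setMethod("show", "ScreenReport", function(object) {
  cat("ScreenReport over",
      length(object@clusterings$structure@tree$labels), "compounds\n")
  for (axis in names(object@clusterings)) {
    t <- supportTable(object@clusterings[[axis]])
    cat(sprintf("  %-9s axis: %d clusters, %d with AU >= 0.95\n", axis,
                nrow(t), sum(t$au >= 0.95)))
  }
  cat("Tree comparisons:\n")
  print(object@comparisons, row.names = FALSE)
})
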