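## Synthetic fixture generation: compounds drawn from scaffold families so
## structural clusters are known; a preferential-attachment PPI graph so
## degree is heavy-tailed; a docking matrix with two planted compound
## groups whose profiles are mirrored over hub vs non-hub proteins. Two
## pairs are planted discordant between the structure and network axes:
## one structurally dissimilar pair shares a docking/network profile, and
## one structurally similar pair is split across profiles.

.scaffoldFamilies <- list(
  alkanol = function(i) paste0(strrep("C", 1 + i), "O"),
  phenol = function(i) paste0(strrep("C", i - 1), "c1ccccc1O"),
  cycloalkane = function(i) paste0(strrep("C", i - 1), "C1CCCCC1"),
  pyran = function(i) paste0(strrep("C", i - 1), "C1CCOCC1")
)

#' Generate a synthetic deep-screen input bundle with planted clusters
#'
#' Produces, bit-exactly reproducible from \code{(seed, parameters)}:
#' \itemize{
#'   \item a SMILES file of \code{nCompounds} compounds drawn from four
#'     scaffold families (alkanols, phenols, cycloalkanes, pyrans) in
#'     contiguous blocks — the structure-axis ground truth;
#'   \item a STRING-style PPI edge TSV from an undirected
#'     preferential-attachment graph over \code{nProteins} proteins
#'     (heavy-tailed degrees); kept edges carry confidences sampled in
#'     [0.7, 0.999] and additional decoy edges below 0.7 exercise the
#'     confidence filter;
#'   \item a docking-score CSV with two planted compound groups: group X
#'     scores high (8-10 before noise) on the \code{nHubProteins}
#'     highest-degree proteins and low elsewhere, group Y the mirror
#'     image, with Gaussian noise (sd 0.5) and clipping to [0, 10] —
#'     the docking/network-axis ground truth.
#' }
#' Group membership is arranged so that one structurally dissimilar pair
#' shares a network profile (\code{truth$pairs$networkConcordant}) and one
#' structurally similar pair splits (\code{truth$pairs$structureSplit}).
#'
#' @param seed integer RNG seed.
#' @param nCompounds number of compounds (>= 4; default 12).
#' @param nProteins number of proteins (>= 6; default 45).
#' @param nHubProteins hub proteins carrying the planted signal (default 5).
#' @param dir output directory (created; default a fresh tempdir).
#' @param noiseSd docking-score noise standard deviation (default 0.5).
#' @return a \linkS4class{FixtureBundle}.
#' @export
generateFixtures <- function(seed, nCompounds = 12, nProteins = 45,
                             nHubProteins = 5, dir = tempfile("fixtures"),
                             noiseSd = 0.5) {
  if (nCompounds < 4) stop("infeasible size: nCompounds must be >= 4")
  if (nProteins < 6) stop("infeasible size: nProteins must be >= 6")
  if (nHubProteins < 1 || nHubProteins >= nProteins / 2)
    stop("infeasible size: need 1 <= nHubProteins < nProteins/2")
  seed <- as.integer(seed)
  set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  ## compounds: contiguous scaffold-family blocks
  nf <- length(.scaffoldFamilies)
  family <- rep(seq_len(nf), each = ceiling(nCompounds / nf))[
    seq_len(nCompounds)]
  variant <- stats::ave(family, family, FUN = seq_along)
  smiles <- vapply(seq_len(nCompounds), function(i)
    .scaffoldFamilies[[family[i]]](variant[i]), character(1))
  ids <- sprintf("cpd%02d", seq_len(nCompounds))
  famNames <- names(.scaffoldFamilies)[family]

  ## planted docking groups with the two discordant pairs
  half <- floor(nCompounds / 2)
  group <- ifelse(seq_len(nCompounds) <= half, "X", "Y")
  if (family[half] != family[half - 1] || family[half + 1] == family[half])
    stop("infeasible size: cannot plant discordant pairs at this nCompounds")
  group[half] <- "Y"          # splits its structural family
  group[half + 1] <- "X"      # joins a structurally alien group
  pairs <- list(networkConcordant = c(ids[1], ids[half + 1]),
                structureSplit = c(ids[half - 1], ids[half]))

  ## PPI graph: preferential attachment, heavy-tailed degrees
  g <- igraph::sample_pa(nProteins, power = 1, m = 2, directed = FALSE)
  prot <- sprintf("P%02d", seq_len(nProteins))
  igraph::V(g)$name <- prot
  deg <- igraph::degree(g)
  hubs <- names(sort(deg, decreasing = TRUE))[seq_len(nHubProteins)]
  el <- igraph::as_edgelist(g)
  confKept <- stats::runif(nrow(el), 0.70, 0.999)
  ## decoy edges below the confidence threshold
  nDecoy <- max(3L, round(nrow(el) * 0.3))
  decoys <- matrix(prot[ceiling(stats::runif(2 * nDecoy) * nProteins)],
                   ncol = 2)
  decoys <- decoys[decoys[, 1] != decoys[, 2], , drop = FALSE]
  keyReal <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  keyDec <- paste(pmin(decoys[, 1], decoys[, 2]),
                  pmax(decoys[, 1], decoys[, 2]))
  decoys <- decoys[!keyDec %in% keyReal & !duplicated(keyDec), ,
                   drop = FALSE]
  confDec <- stats::runif(nrow(decoys), 0.15, 0.69)

  ## docking scores: mirrored hub/non-hub profiles plus Gaussian noise
  isHub <- prot %in% hubs
  base <- matrix(0, nCompounds, nProteins,
                 dimnames = list(ids, prot))
  for (i in seq_len(nCompounds)) {
    hi <- stats::runif(1, 8.5, 9.5)      # per-compound high plateau
    lo <- stats::runif(1, 2.0, 3.0)
    base[i, ] <- if (group[i] == "X") ifelse(isHub, hi, lo)
                 else ifelse(isHub, lo, hi)
  }
  scores <- base + matrix(stats::rnorm(length(base), 0, noiseSd),
                          nrow(base))
  scores <- pmin(pmax(scores, 0), 10)

  ## write files
  smiFile <- file.path(dir, "compounds.smi")
  writeLines(paste(smiles, ids, sep = "\t"), smiFile)
  ppiFile <- file.path(dir, "ppi_edges.tsv")
  allEl <- rbind(el, decoys)
  allConf <- round(c(confKept, confDec) * 1000)
  writeLines(c("protein1\tprotein2\tcombined_score",
               paste(allEl[, 1], allEl[, 2], allConf, sep = "\t")),
             ppiFile)
  dockFile <- file.path(dir, "docking_scores.csv")
  .writeLabelledCsv(round(scores, 6), dockFile)
  truthFile <- file.path(dir, "truth_labels.csv")
  utils::write.csv(data.frame(compound = ids, structure = famNames,
                              docking = group, network = group),
                   truthFile, row.names = FALSE, quote = TRUE)

  truth <- list(structure = stats::setNames(famNames, ids),
                docking = stats::setNames(group, ids),
                network = stats::setNames(group, ids),
                hubs = hubs, pairs = pairs)
  new("FixtureBundle", dir = dir,
      files = list(smiles = smiFile, docking = dockFile, ppi = ppiFile,
                   truth = truthFile),
      truth = truth, seed = seed,
      params = list(nCompounds = nCompounds, nProteins = nProteins,
                    nHubProteins = nHubProteins, noiseSd = noiseSd))
}

setMethod("show", "FixtureBundle", function(object) {
  cat("FixtureBundle (seed ", object@seed, "): ",
      object@params$nCompounds, " compounds, ",
      object@params$nProteins, " proteins in ", object@dir, "\n", sep = "")
})

#' Packaged ageing-compound screen fixture
#'
#' The package ships a small static input set mirroring a published
#' ageing-related compound screen: 12 test compounds (rapamycin,
#' vitamin C, retinol, retinoic acid, resveratrol, metformin, salicylic
#' acid and derivatives, a jasmonate derivative and a C-xyloside) with
#' well-known SMILES, and the 45 docked protein targets of that screen
#' with their PPI node degrees. Docking scores for this panel came from
#' an external docking service and are not redistributed; use
#' \code{\link{generateFixtures}} for a complete synthetic input bundle.
#'
#' @return list with elements \code{compounds} (a
#'   \linkS4class{CompoundSet} of 12) and \code{degrees} (named integer
#'   vector over 45 proteins).
#' @export
ageingFixture <- function() {
  smi <- system.file("extdata", "ageing_compounds.smi",
                     package = "deepscreen", mustWork = TRUE)
  deg <- system.file("extdata", "ageing_protein_degrees.tsv",
                     package = "deepscreen", mustWork = TRUE)
  tab <- utils::read.delim(deg, stringsAsFactors = FALSE)
  list(compounds = loadCompounds(smi, format = "smiles"),
       degrees = stats::setNames(as.integer(tab$degree), tab$protein))
}
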