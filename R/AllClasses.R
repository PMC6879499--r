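#' @import methods
NULL

#' CompoundSet: an ordered collection of parsed small molecules
#'
#' Holds the parsed heavy-atom connectivity of a set of compounds, in file
#' order. The order is preserved into the rows/columns of every matrix
#' derived from the set. Structures are stored as simple molecular graphs
#' (element, aromaticity flag per atom; bond list with orders, aromatic
#' bonds carry order 1.5) after stripping explicit hydrogens and
#' re-perceiving aromaticity from kekulized input.
#'
#' @slot ids character, unique compound identifiers.
#' @slot compoundNames character, free-text names (may equal ids).
#' @slot smiles character, canonical SMILES as re-exported by the parser.
#' @slot graphs list of molecular graphs (see \code{\link{molGraph}}).
#' @slot sourceFormat character scalar, one of \code{"sdf"}, \code{"mol"},
#'   \code{"smiles"}.
#'
#' @seealso \code{\link{loadCompounds}}, \code{\link{similarityMatrix}}
#' @export
setClass("CompoundSet",
  representation(
    ids = "character",
    compoundNames = "character",
    smiles = "character",
    graphs = "list",
    sourceFormat = "character"
  )
)

setValidity("CompoundSet", function(object) {
  n <- length(object@ids)
  if (anyDuplicated(object@ids))
    return("compound ids must be unique")
  if (length(object@graphs) != n || length(object@smiles) != n ||
      length(object@compoundNames) != n)
    return("ids, names, smiles and graphs must have equal length")
  heavy <- vapply(object@graphs, function(g) length(g$elements), integer(1))
  if (n > 0 && any(heavy < 1))
    return("every compound must have at least one heavy atom")
  TRUE
})

#' SimilarityMatrix: pairwise compound structural similarity
#'
#' A symmetric compound-by-compound matrix of similarities in [0, 1] with
#' unit diagonal. The \code{method} slot records how it was computed:
#' \code{"mcs_overlap"} (maximum-common-substructure overlap coefficient
#' n/min(c1, c2)) or \code{"morgan_tanimoto"} (Tanimoto similarity of
#' hashed circular fingerprints).
#'
#' @slot .Data numeric matrix with compound ids as dimnames.
#' @slot method character scalar.
#' @export
setClass("SimilarityMatrix", contains = "matrix",
  representation(method = "character"))

setValidity("SimilarityMatrix", function(object) {
  m <- object@.Data
  if (nrow(m) != ncol(m)) return("must be square")
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
    return("row and column labels must be identical compound ids")
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-12)))
    return("must be symmetric")
  if (any(m < -1e-12 | m > 1 + 1e-12)) return("entries must lie in [0, 1]")
  if (any(abs(diag(m) - 1) > 1e-12)) return("diagonal must be 1")
  if (!object@method %in% c("mcs_overlap", "morgan_tanimoto"))
    return("unknown similarity method")
  TRUE
})

#' DockingScoreMatrix: compound-by-protein docking scores
#'
#' Scores are on the 0-10 pKd/pKi scale (negative log10 of a predicted
#' dissociation/association constant) as produced by an external docking
#' service; cells may be missing (NA). Canonical orientation is compounds
#' in rows, proteins in columns.
#'
#' @slot .Data numeric matrix, compounds x proteins, entries in [0, 10] or NA.
#' @export
setClass("DockingScoreMatrix", contains = "matrix")

setValidity("DockingScoreMatrix", function(object) {
  m <- object@.Data
  if (is.null(rownames(m)) || is.null(colnames(m)))
    return("compound and protein ids required as dimnames")
  if (anyDuplicated(rownames(m))) return("duplicate compound ids")
  if (anyDuplicated(colnames(m))) return("duplicate protein ids")
  if (nrow(m) < 2 || ncol(m) < 2)
    return("need at least 2 compounds and 2 proteins")
  v <- m[!is.na(m)]
  if (length(v) && (min(v) < 0 || max(v) > 10))
    return("docking scores must lie in [0, 10]")
  TRUE
})

#' RankMatrix: per-compound descending ranks of docking scores
#'
#' Each compound row holds the ranks of its docking scores across the
#' protein panel, rank 1 for the highest score, ties averaged. Over the
#' p non-missing proteins of a row the ranks sum to p(p+1)/2.
#'
#' @slot .Data numeric matrix, compounds x proteins, ranks >= 1 or NA.
#' @export
setClass("RankMatrix", contains = "matrix")

setValidity("RankMatrix", function(object) {
  m <- object@.Data
  if (is.null(rownames(m)) || is.null(colnames(m)))
    return("compound and protein ids required as dimnames")
  v <- m[!is.na(m)]
  if (length(v) && min(v) < 1) return("ranks must be >= 1")
  ok <- vapply(seq_len(nrow(m)), function(i) {
    r <- m[i, ]; r <- r[!is.na(r)]; p <- length(r)
    p == 0 || isTRUE(all.equal(sum(r), p * (p + 1) / 2))
  }, logical(1))
  if (!all(ok)) return("row rank sums must equal p(p+1)/2")
  TRUE
})

#' NetworkEffectMatrix: degree-weighted docking rank profiles
#'
#' effect(c, p) = rank(c, p) * degree(p): the per-compound docking rank of
#' protein p multiplied by p's node degree in the protein-protein
#' interaction network, amplifying binding to network hubs.
#'
#' @slot .Data numeric matrix, compounds x proteins, entries >= 0 or NA.
#' @export
setClass("NetworkEffectMatrix", contains = "matrix")

setValidity("NetworkEffectMatrix", function(object) {
  m <- object@.Data
  if (is.null(rownames(m)) || is.null(colnames(m)))
    return("compound and protein ids required as dimnames")
  v <- m[!is.na(m)]
  if (length(v) && min(v) < 0) return("effects must be non-negative")
  TRUE
})

#' DissimilarityMatrix: correlation-based dissimilarity between items
#'
#' d(i, j) = 1 - Pearson correlation of the items' feature profiles;
#' symmetric, zero diagonal, entries in [0, 2].
#'
#' @slot .Data numeric matrix with item ids as dimnames.
#' @export
setClass("DissimilarityMatrix", contains = "matrix")

setValidity("DissimilarityMatrix", function(object) {
  m <- object@.Data
  if (nrow(m) != ncol(m)) return("must be square")
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
    return("row and column labels must match")
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-12)))
    return("must be symmetric")
  if (any(abs(diag(m)) > 1e-12)) return("diagonal must be 0")
  if (any(m < -1e-12 | m > 2 + 1e-12)) return("entries must lie in [0, 2]")
  TRUE
})

#' McsResult: a single maximum-common-substructure comparison
#'
#' @slot n integer, heavy atoms in the maximum common connected substructure.
#' @slot c1,c2 integer, heavy-atom counts of the two input compounds.
#' @slot coefficient numeric, overlap coefficient n/min(c1, c2).
#' @slot timedOut logical, TRUE when the search hit its time budget and
#'   \code{n} is the best size found so far (a lower bound).
#' @export
setClass("McsResult",
  representation(n = "integer", c1 = "integer", c2 = "integer",
                 coefficient = "numeric", timedOut = "logical"))

setValidity("McsResult", function(object) {
  if (object@n < 0) return("n must be non-negative")
  if (object@n > min(object@c1, object@c2))
    return("n cannot exceed min(c1, c2)")
  TRUE
})

#' ClusterSupport: multiscale-bootstrap support for a cluster tree
#'
#' Per internal cluster of an observed dendrogram: the raw bootstrap
#' probability at scale 1 (BP), the approximately unbiased p-value (AU)
#' from the multiscale probit fit, the fitted signed distance \code{v} and
#' curvature \code{c}, their standard errors, and the per-scale hit counts.
#'
#' @slot table data.frame with one row per internal cluster: cluster,
#'   members, au, bp, v, c, seAu, seBp, degenerate.
#' @slot counts list, per cluster an integer matrix with rows
#'   \code{hits} and \code{nboot}, one column per scale.
#' @slot scales numeric, relative resampling scales r.
#' @slot nboot integer, replicates per scale.
#' @slot seed integer, root RNG seed.
#' @slot linkage character, agglomeration method.
#' @export
setClass("ClusterSupport",
  representation(table = "data.frame", counts = "list", scales = "numeric",
                 nboot = "integer", seed = "integer", linkage = "character"))

setValidity("ClusterSupport", function(object) {
  t <- object@table
  need <- c("cluster", "members", "au", "bp", "v", "c", "degenerate")
  if (!all(need %in% names(t)))
    return(paste("support table must contain:", paste(need, collapse = ", ")))
  if (nrow(t) && (any(t$au < -1e-9 | t$au > 1 + 1e-9) ||
                  any(t$bp < -1e-9 | t$bp > 1 + 1e-9)))
    return("AU and BP must lie in [0, 1]")
  TRUE
})

#' CompoundClustering: a dendrogram over compounds with bootstrap support
#'
#' Couples the observed hierarchical cluster tree (a \code{stats::hclust}
#' object) with its \linkS4class{ClusterSupport} and the name of the axis
#' it was computed on.
#'
#' @slot tree hclust object.
#' @slot support ClusterSupport.
#' @slot axis character, e.g. "structure", "docking", "network".
#' @export
setClass("CompoundClustering",
  representation(tree = "ANY", support = "ClusterSupport",
                 axis = "character"))

setValidity("CompoundClustering", function(object) {
  if (!inherits(object@tree, "hclust")) return("tree must be an hclust")
  if (is.null(object@tree$labels)) return("tree must carry leaf labels")
  TRUE
})

#' FixtureBundle: synthetic inputs with planted ground truth
#'
#' File paths of a generated compound/docking/PPI input set, the exact
#' generator parameters, and the ground-truth partition labels for each
#' clustering axis. Regenerable bit-exactly from (seed, params).
#'
#' @slot dir character, directory holding the files.
#' @slot files named list of file paths (smiles, docking, ppi, truth).
#' @slot truth named list of ground-truth label vectors
#'   (structure, docking, network) plus the planted discordant pairs.
#' @slot seed integer.
#' @slot params named list of generator parameters.
#' @export
setClass("FixtureBundle",
  representation(dir = "character", files = "list", truth = "list",
                 seed = "integer", params = "list"))

#' ScreenReport: results of a full three-axis deep screen
#'
#' @slot clusterings named list of three \linkS4class{CompoundClustering}
#'   objects (structure, docking, network) over an identical leaf set.
#' @slot comparisons data.frame of pairwise tree-comparison records
#'   (axes, k, adjustedRand, fowlkesMallows, copheneticCorrelation).
#' @slot metadata list: config echo, package version, warnings, timestamps.
#' @export
setClass("ScreenReport",
  representation(clusterings = "list", comparisons = "data.frame",
                 metadata = "list"))

setValidity("ScreenReport", function(object) {
  cl <- object@clusterings
  if (length(cl) != 3) return("expect exactly three clusterings")
  leaves <- lapply(cl, function(x) sort(x@tree$labels))
  if (!all(vapply(leaves, identical, logical(1), y = leaves[[1]])))
    return("all three trees must share the same compound leaf set")
  TRUE
})
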