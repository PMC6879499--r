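#' @include AllClasses.R
NULL

#' Compound identifiers of an object
#' @param x a CompoundSet or a compound-indexed matrix class.
#' @return character vector of compound ids, in object order.
#' @export
setGeneric("compoundIds", function(x) standardGeneric("compoundIds"))

#' Protein identifiers of an object
#' @param x a protein-indexed matrix class.
#' @return character vector of protein ids.
#' @export
setGeneric("proteinIds", function(x) standardGeneric("proteinIds"))

#' Number of compounds in an object
#' @param x a CompoundSet.
#' @return integer count.
#' @export
setGeneric("nCompounds", function(x) standardGeneric("nCompounds"))

#' Pairwise structural similarity matrix of a compound set
#'
#' @param set a \linkS4class{CompoundSet} of at least two compounds.
#' @param method \code{"mcs_overlap"} (default) or \code{"morgan_tanimoto"}.
#' @param ... method parameters: \code{params} (an \code{\link{mcsParams}}
#'   object) for \code{mcs_overlap}; \code{radius} and \code{nBits} for
#'   \code{morgan_tanimoto}.
#' @return a \linkS4class{SimilarityMatrix}.
#' @export
setGeneric("similarityMatrix",
  function(set, method = c("mcs_overlap", "morgan_tanimoto"), ...)
    standardGeneric("similarityMatrix"))

#' Rank-normalize a docking-score matrix
#'
#' Replaces each compound's docking scores with descending ranks (1 = the
#' compound's highest score), ties resolved by averaging the positions
#' they span. Ranking removes the compound-size enthalpy bias of raw
#' docking scores so profiles of differently sized compounds compare.
#'
#' @param m a \linkS4class{DockingScoreMatrix}.
#' @return a \linkS4class{RankMatrix}.
#' @export
setGeneric("rankNormalize", function(m) standardGeneric("rankNormalize"))

#' Degree-weighted network-effect matrix
#'
#' Multiplies each rank-normalized docking score by the node degree of the
#' target protein in a protein-protein interaction network, amplifying
#' binding events on network hubs.
#'
#' @param ranks a \linkS4class{RankMatrix}.
#' @param degrees named integer vector of protein degrees (see
#'   \code{\link{nodeDegrees}}).
#' @param missingPolicy what to do with rank proteins absent from
#'   \code{degrees}: \code{"zero"} (default; degree 0), \code{"drop"}
#'   (remove the column), \code{"error"}.
#' @return a \linkS4class{NetworkEffectMatrix}.
#' @export
setGeneric("networkEffect",
  function(ranks, degrees, missingPolicy = c("zero", "drop", "error"))
    standardGeneric("networkEffect"))

#' Compare two compound dendrograms
#'
#' Cuts both trees into k flat clusters and reports the adjusted Rand
#' index and Fowlkes-Mallows index of the two partitions, plus the
#' Pearson correlation of the trees' cophenetic distance vectors.
#'
#' @param a,b trees over an identical leaf set (hclust or
#'   \linkS4class{CompoundClustering}).
#' @param k integer number of flat clusters, 2 <= k <= number of leaves.
#' @return one-row data.frame: k, adjustedRand, fowlkesMallows,
#'   copheneticCorrelation.
#' @export
setGeneric("compareTrees", function(a, b, k) standardGeneric("compareTrees"))

#' Serialize a cluster tree to Newick
#'
#' Branch lengths follow the ultrametric convention (leaf depth = half the
#' merge height); when support is supplied, internal nodes are labelled
#' with their AU p-values.
#'
#' @param tree an hclust or \linkS4class{CompoundClustering}.
#' @param support optional \linkS4class{ClusterSupport} (taken from the
#'   object when a CompoundClustering is given).
#' @return a Newick string (terminated by ";").
#' @export
setGeneric("toNewick",
  function(tree, support = NULL) standardGeneric("toNewick"))

#' Support table accessor
#' @param x a CompoundClustering or ClusterSupport.
#' @return data.frame of per-cluster AU/BP support.
#' @export
setGeneric("supportTable", function(x) standardGeneric("supportTable"))
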