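.asHclust <- function(x) {
  if (is(x, "CompoundClustering")) x@tree
  else if (inherits(x, "hclust")) x
  else stop("expected an hclust or CompoundClustering")
}

.compareTreesImpl <- function(a, b, k) {
  ta <- .asHclust(a); tb <- .asHclust(b)
  la <- sort(ta$labels); lb <- sort(tb$labels)
  if (!identical(la, lb))
    stop("leaf sets differ: ",
         paste(c(setdiff(la, lb), setdiff(lb, la)), collapse = ", "))
  L <- length(la)
  if (k < 2 || k > L) stop("k must satisfy 2 <= k <= ", L)
  pa <- stats::cutree(ta, k = k)[la]
  pb <- stats::cutree(tb, k = k)[la]
  ari <- mclust::adjustedRandIndex(pa, pb)
  fm <- .fowlkesMallows(pa, pb)
  ## k = L cuts both trees into singletons: no co-clustered pairs exist,
  ## and agreement on that empty pair set is perfect
  if (is.nan(ari) || is.na(fm)) {
    same <- .partitionsEqual(pa, pb)
    if (is.nan(ari)) ari <- if (same) 1 else NA_real_
    if (is.na(fm)) fm <- if (same) 1 else NA_real_
  }
  ca <- as.matrix(stats::cophenetic(ta))[la, la]
  cb <- as.matrix(stats::cophenetic(tb))[la, la]
  lower <- lower.tri(ca)
  cc <- if (stats::sd(ca[lower]) == 0 || stats::sd(cb[lower]) == 0) {
    if (isTRUE(all.equal(ca[lower], cb[lower]))) 1 else NA_real_
  } else stats::cor(ca[lower], cb[lower])
  data.frame(k = k, adjustedRand = ari, fowlkesMallows = fm,
             copheneticCorrelation = cc)
}

## Fowlkes-Mallows index from the contingency table of two partitions:
## Tk / sqrt(Pk * Qk) with Tk = sum n_ij^2 - n, Pk = sum n_i.^2 - n,
## Qk = sum n_.j^2 - n
.partitionsEqual <- function(pa, pb) {
  all(vapply(seq_along(pa), function(i)
    identical(pa == pa[i], pb == pb[i]), logical(1)))
}

.fowlkesMallows <- function(pa, pb) {
  n <- length(pa)
  tab <- table(pa, pb)
  Tk <- sum(tab^2) - n
  Pk <- sum(rowSums(tab)^2) - n
  Qk <- sum(colSums(tab)^2) - n
  if (Pk == 0 || Qk == 0) return(NA_real_)
  Tk / sqrt(Pk * Qk)
}

#' @rdname compareTrees
#' @aliases compareTrees,ANY,ANY-method
setMethod("compareTrees", signature(a = "ANY", b = "ANY"),
          function(a, b, k) .compareTreesImpl(a, b, k))

.newickFromHclust <- function(hc, nodeLabels = NULL) {
  merge <- hc$merge
  heights <- hc$height
  labels <- hc$labels
  quote <- function(s) gsub("[(),:;[:space:]]", "_", s)
  build <- function(node, parentHeight) {
    if (node < 0) {
      paste0(quote(labels[-node]), ":",
             format(parentHeight / 2, digits = 10))
    } else {
      h <- heights[node]
      lab <- if (!is.null(nodeLabels)) {
        v <- nodeLabels[node]
        if (is.na(v)) "" else format(v, digits = 6)
      } else ""
      len <- if (is.na(parentHeight)) "" else
        paste0(":", format((parentHeight - h) / 2, digits = 10))
      paste0("(", build(merge[node, 1], h), ",",
             build(merge[node, 2], h), ")", lab, len)
    }
  }
  paste0(build(nrow(merge), NA), ";")
}

#' @rdname toNewick
#' @aliases toNewick,CompoundClustering-method
setMethod("toNewick", "CompoundClustering", function(tree, support = NULL) {
  au <- auValues(tree)
  .newickFromHclust(tree@tree, nodeLabels = au)
})

#' @rdname toNewick
#' @aliases toNewick,ANY-method
setMethod("toNewick", "ANY", function(tree, support = NULL) {
  hc <- .asHclust(tree)
  labs <- NULL
  if (!is.null(support)) labs <- support@table$au
  .newickFromHclust(hc, nodeLabels = labs)
})

#' Write a tree as a Newick file
#' @param tree hclust or CompoundClustering.
#' @param path output .nwk file.
#' @param support optional ClusterSupport for node labels.
#' @return invisibly, the path.
#' @export
writeNewick <- function(tree, path, support = NULL) {
  writeLines(if (is(tree, "CompoundClustering")) toNewick(tree)
             else toNewick(tree, support), path)
  invisible(path)
}
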