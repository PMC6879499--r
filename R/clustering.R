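#' Correlation-based dissimilarity between item feature profiles
#'
#' d(i, j) = 1 - Pearson correlation of rows i and j of the feature
#' matrix. Values in [0, 2]: 0 for identical profiles (up to affine
#' scaling), 2 for exactly anticorrelated ones. Tiny negative values from
#' floating-point rounding are clamped to 0.
#'
#' @param features numeric matrix, items in rows (rownames required),
#'   features in columns; at least 2 items and 3 features, each item with
#'   positive feature variance.
#' @return a \linkS4class{DissimilarityMatrix}.
#' @export
correlationDissimilarity <- function(features) {
  features <- as.matrix(features)
  if (is.null(rownames(features))) stop("features must have row names")
  if (nrow(features) < 2) stop("need at least 2 items")
  if (ncol(features) < 3) stop("need at least 3 features per item")
  v <- apply(features, 1, stats::var)
  if (any(v == 0 | is.na(v)))
    stop("zero feature variance for item(s): ",
         paste(rownames(features)[v == 0 | is.na(v)], collapse = ", "),
         " (correlation undefined)")
  d <- 1 - stats::cor(t(features))
  d[d < 0 & d > -1e-8] <- 0
  d[d > 2 & d < 2 + 1e-8] <- 2
  diag(d) <- 0
  d <- (d + t(d)) / 2
  new("DissimilarityMatrix", d)
}

#' Agglomerative hierarchical clustering of a dissimilarity matrix
#'
#' A thin, validated wrapper over \code{stats::hclust}. \code{"ward"}
#' maps to \code{"ward.D2"} (squared-distance update on unsquared input).
#' The agglomeration is deterministic for a fixed input matrix; equal-
#' distance merge ties are resolved by \code{hclust}'s fixed internal
#' scan order, so repeated runs produce identical trees.
#'
#' @param d a \linkS4class{DissimilarityMatrix} (or symmetric labelled
#'   matrix with zero diagonal).
#' @param linkage one of "average" (default), "complete", "single", "ward".
#' @return an object of class \code{hclust}.
#' @export
hierarchicalCluster <- function(d, linkage = c("average", "complete",
                                               "single", "ward")) {
  linkage <- match.arg(linkage)
  m <- as(d, "matrix")
  if (nrow(m) != ncol(m) || !isTRUE(all.equal(m, t(m), tolerance = 1e-8)))
    stop("dissimilarity matrix must be square and symmetric")
  method <- if (linkage == "ward") "ward.D2" else linkage
  stats::hclust(stats::as.dist(m), method = method)
}

## leaf-id sets of every internal node of an hclust, in merge order
.clusterLeafSets <- function(hc) {
  labels <- hc$labels
  n <- length(labels)
  sets <- vector("list", n - 1)
  for (i in seq_len(n - 1)) {
    members <- integer(0)
    for (child in hc$merge[i, ]) {
      members <- c(members,
                   if (child < 0) -child else sets[[child]])
    }
    sets[[i]] <- sort(members)
  }
  lapply(sets, function(s) labels[s])
}

#' Probit scaling-curve fit for one cluster's multiscale BP values
#'
#' Fits qnorm(1 - BP_r) = v * sqrt(r) + c / sqrt(r) by weighted least
#' squares, weights from the binomial variance of BP_r. In terms of the
#' theoretical scale sigma = 1/sqrt(r), v is the coefficient of 1/sigma
#' (the signed distance of the cluster boundary) and c the coefficient of
#' sigma (its curvature). The approximately unbiased p-value is
#' AU = 1 - pnorm(v - c) and the smoothed bootstrap probability
#' 1 - pnorm(v + c); at r = 1 the fit reproduces
#' qnorm(1 - BP_1) = v + c. BP values are clipped
#' to [1/(2B), 1 - 1/(2B)] before the probit transform; clipped scales
#' receive near-zero weight through the dnorm^2 factor. With a single
#' scale the fit degenerates to classical bootstrap: v = z, c = 0, so AU
#' and the smoothed BP both equal the raw bootstrap probability. When
#' every BP_r sits on the same {0, 1} boundary no fit is attempted and AU
#' is set to that boundary with the degenerate flag raised.
#'
#' @param bp numeric vector of per-scale bootstrap probabilities.
#' @param scales numeric vector of resampling scales r (same length).
#' @param nboot replicates per scale (scalar or vector).
#' @return list(au, bp, v, c, seAu, seBp, degenerate).
#' @export
fitScalingCurve <- function(bp, scales, nboot) {
  stopifnot(length(bp) == length(scales))
  B <- rep_len(nboot, length(bp))
  if (all(bp %in% c(0, 1))) {
    boundary <- as.numeric(mean(bp) >= 0.5)
    return(list(au = boundary, bp = boundary, v = NA_real_, c = NA_real_,
                seAu = NA_real_, seBp = NA_real_, degenerate = TRUE))
  }
  eps <- 1 / (2 * B)
  bpc <- pmin(pmax(bp, eps), 1 - eps)
  z <- stats::qnorm(1 - bpc)
  sqrtR <- sqrt(scales)
  w <- B * stats::dnorm(z)^2 / (bpc * (1 - bpc))
  if (length(scales) == 1) {
    v <- z; cc <- 0
    au <- 1 - stats::pnorm(v - cc)
    se <- sqrt(bpc * (1 - bpc) / B)
    return(list(au = au, bp = au, v = v, c = cc, seAu = se, seBp = se,
                degenerate = FALSE))
  }
  X <- cbind(sqrtR, 1 / sqrtR)
  XtWX <- crossprod(X * sqrt(w))
  if (abs(det(XtWX)) < 1e-12) {
    ## no usable information across scales; fall back to scale-1 behavior
    v <- stats::weighted.mean(z, w); cc <- 0
    au <- 1 - stats::pnorm(v)
    return(list(au = au, bp = au, v = v, c = cc, seAu = NA_real_,
                seBp = NA_real_, degenerate = TRUE))
  }
  beta <- solve(XtWX, crossprod(X * w, z))
  v <- beta[1]; cc <- beta[2]
  covB <- solve(XtWX)
  varDiff <- covB[1, 1] + covB[2, 2] - 2 * covB[1, 2]
  varSum <- covB[1, 1] + covB[2, 2] + 2 * covB[1, 2]
  au <- 1 - stats::pnorm(v - cc)
  bps <- 1 - stats::pnorm(v + cc)
  list(au = au, bp = bps, v = v, c = cc,
       seAu = stats::dnorm(v - cc) * sqrt(max(varDiff, 0)),
       seBp = stats::dnorm(v + cc) * sqrt(max(varSum, 0)),
       degenerate = FALSE)
}

#' Hierarchical clustering with multiscale-bootstrap AU support
#'
#' Clusters items by correlation dissimilarity of their feature profiles,
#' then assesses every internal cluster of the observed dendrogram by
#' multiscale bootstrap: for each relative scale r, feature columns are
#' resampled with replacement to size round(r * n_features), the items
#' reclustered, and the fraction of replicates in which the cluster's
#' exact leaf set reappears recorded as BP_r. The scaling curve of
#' probit-transformed BP values across scales yields the approximately
#' unbiased p-value AU (see \code{\link{fitScalingCurve}}), which corrects
#' the bias of the classical bootstrap probability. The root cluster is
#' assigned support 1 by convention.
#'
#' Per-scale RNG streams are derived deterministically from the root
#' seed, so results are reproducible and independent of evaluation order.
#' A bootstrap replicate whose resampled features leave an item with zero
#' variance contributes max dissimilarity for the affected pairs.
#'
#' @param features numeric matrix, items (to cluster) in rows, features
#'   in columns; rownames required.
#' @param linkage agglomeration method (default "average").
#' @param scales relative resampling scales (default 0.5 to 1.4 by 0.1;
#'   \code{scales = 1} gives the classical bootstrap).
#' @param nboot bootstrap replicates per scale (default 1000).
#' @param seed integer root seed (mandatory for reproducibility).
#' @param axis label stored on the result (e.g. "structure").
#' @return a \linkS4class{CompoundClustering}.
#' @export
multiscaleBootstrap <- function(features, linkage = "average",
                                scales = seq(0.5, 1.4, by = 0.1),
                                nboot = 1000, seed, axis = "features") {
  if (missing(seed)) stop("seed is mandatory for bootstrap reproducibility")
  seed <- as.integer(seed)
  nboot <- as.integer(nboot)
  if (nboot < 1) stop("nboot must be >= 1")
  if (any(scales <= 0)) stop("scales must be positive")
  features <- as.matrix(features)
  nf <- ncol(features)
  sizes <- round(scales * nf)
  if (any(sizes < 3))
    stop("scale(s) ", paste(scales[sizes < 3], collapse = ", "),
         " give a resample of < 3 features")
  d0 <- correlationDissimilarity(features)
  hc <- hierarchicalCluster(d0, linkage)
  leafSets <- .clusterLeafSets(hc)
  keys <- vapply(leafSets, paste, character(1), collapse = "\r")
  nClus <- length(keys)
  hits <- matrix(0L, nClus, length(scales))
  for (si in seq_along(scales)) {
    set.seed((seed + 7919L * si) %% .Machine$integer.max)
    m <- sizes[si]
    for (b in seq_len(nboot)) {
      idx <- sample.int(nf, m, replace = TRUE)
      sub <- features[, idx, drop = FALSE]
      dd <- 1 - suppressWarnings(stats::cor(t(sub)))
      dd[is.na(dd)] <- 1
      diag(dd) <- 0
      bhc <- stats::hclust(stats::as.dist((dd + t(dd)) / 2),
                           method = hc$method)
      bsets <- .clusterLeafSets(bhc)
      bkeys <- vapply(bsets, paste, character(1), collapse = "\r")
      hit <- keys %in% bkeys
      hits[hit, si] <- hits[hit, si] + 1L
    }
  }
  bpMat <- hits / nboot
  rows <- vector("list", nClus)
  counts <- vector("list", nClus)
  scale1 <- which.min(abs(scales - 1))
  for (i in seq_len(nClus)) {
    isRoot <- length(leafSets[[i]]) == length(hc$labels)
    fit <- if (isRoot)
      list(au = 1, bp = 1, v = 0, c = 0, seAu = 0, seBp = 0,
           degenerate = FALSE)
    else fitScalingCurve(bpMat[i, ], scales, nboot)
    rows[[i]] <- data.frame(
      cluster = paste0("c", i),
      members = paste(leafSets[[i]], collapse = ","),
      au = min(max(fit$au, 0), 1),
      bp = min(max(fit$bp, 0), 1),
      bpRaw = bpMat[i, scale1],
      v = fit$v, c = fit$c, seAu = fit$seAu, seBp = fit$seBp,
      degenerate = fit$degenerate,
      stringsAsFactors = FALSE)
    counts[[i]] <- rbind(hits = hits[i, ], nboot = rep(nboot,
                                                       length(scales)))
  }
  tab <- do.call(rbind, rows)
  names(counts) <- tab$cluster
  support <- new("ClusterSupport", table = tab, counts = counts,
                 scales = scales, nboot = nboot, seed = seed,
                 linkage = linkage)
  new("CompoundClustering", tree = hc, support = support, axis = axis)
}

#' @rdname supportTable
#' @aliases supportTable,ClusterSupport-method
setMethod("supportTable", "ClusterSupport", function(x) x@table)
#' @rdname supportTable
#' @aliases supportTable,CompoundClustering-method
setMethod("supportTable", "CompoundClustering",
          function(x) x@support@table)

#' AU p-values of a clustering, in merge order
#' @param x a CompoundClustering.
#' @return numeric vector named by cluster id.
#' @export
auValues <- function(x) {
  t <- supportTable(x)
  stats::setNames(t$au, t$cluster)
}

setMethod("show", "ClusterSupport", function(object) {
  cat("ClusterSupport:", nrow(object@table), "clusters;",
      length(object@scales), "scales x", object@nboot,
      "replicates; linkage =", object@linkage, "\n")
  print(utils::head(object@table[, c("cluster", "members", "au", "bp")],
                    10), row.names = FALSE)
})

setMethod("show", "CompoundClustering", function(object) {
  cat("CompoundClustering [", object@axis, "] over ",
      length(object@tree$labels), " compounds (linkage ",
      object@tree$method, ")\n", sep = "")
  show(object@support)
})

#' Plot a support-annotated dendrogram
#'
#' Draws the observed dendrogram with AU p-values (as percentages) at the
#' internal nodes.
#'
#' @param x a \linkS4class{CompoundClustering}.
#' @param main plot title (defaults to the axis name).
#' @param ... passed to \code{plot.hclust}.
#' @return invisibly, NULL.
#' @export
plotSupport <- function(x, main = NULL, ...) {
  hc <- x@tree
  if (is.null(main)) main <- paste("Cluster dendrogram:", x@axis)
  graphics::plot(hc, main = main, sub = "", xlab = "",
                 ylab = "dissimilarity", ...)
  coords <- .mergeCoords(hc)
  au <- supportTable(x)$au
  graphics::text(coords$x, coords$y, labels = sprintf("%.0f", 100 * au),
                 col = "red", pos = 3, cex = 0.8, offset = 0.2)
  invisible(NULL)
}

## x/y plotting coordinates of each internal node of an hclust
.mergeCoords <- function(hc) {
  n <- length(hc$labels)
  leafX <- numeric(n)
  leafX[hc$order] <- seq_len(n)
  x <- numeric(n - 1)
  for (i in seq_len(n - 1)) {
    cx <- vapply(hc$merge[i, ], function(ch)
      if (ch < 0) leafX[-ch] else x[ch], numeric(1))
    x[i] <- mean(cx)
  }
  list(x = x, y = hc$height)
}

#' Write a cluster support table as CSV
#' @param x a CompoundClustering or ClusterSupport.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeSupportTable <- function(x, path) {
  utils::write.csv(supportTable(x), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
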