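#' Parameters for the maximum-common-substructure search
#'
#' The search finds the largest connected substructure (in heavy atoms)
#' shared by two molecules. By default matching is strict: identical
#' elements, identical aromaticity, identical bond orders. The mismatch
#' budgets relax matching in the spirit of flexible-MCS algorithms, which
#' tolerate small atom/bond mismatches to recover local similarities
#' between molecules of very different size; the exact mismatch search of
#' published FMCS implementations is backend-specific, so budgets here are
#' simple global counts (default 0).
#'
#' @param timeout per-pair time budget in seconds; on expiry the best size
#'   found so far is returned with \code{timedOut = TRUE} (never silently).
#' @param matchBondOrder require equal bond orders along the common
#'   substructure (aromatic bonds count as order 1.5, so an aromatic ring
#'   never maps onto an aliphatic chain).
#' @param matchAromatic additionally require equal atom aromaticity flags
#'   (default FALSE: atom identity is the element; aromaticity already
#'   constrains the mapping through bond orders, and element-only atom
#'   matching guarantees n >= 1 whenever the element sets intersect).
#' @param ringMatchesRing when TRUE a ring bond may only map to a ring bond.
#' @param connected require the common substructure to be connected
#'   (standard FMCS semantics); when FALSE, components are accumulated
#'   greedily by repeated connected searches on the unmapped remainder.
#' @param atomMismatch number of atom-element mismatches tolerated.
#' @param bondMismatch number of bond-order mismatches tolerated.
#' @return an object of class \code{mcsParams} (a named list).
#' @export
mcsParams <- function(timeout = 10, matchBondOrder = TRUE,
                      matchAromatic = FALSE, ringMatchesRing = FALSE,
                      connected = TRUE, atomMismatch = 0L,
                      bondMismatch = 0L) {
  structure(list(timeout = timeout, matchBondOrder = matchBondOrder,
                 matchAromatic = matchAromatic,
                 ringMatchesRing = ringMatchesRing, connected = connected,
                 atomMismatch = as.integer(atomMismatch),
                 bondMismatch = as.integer(bondMismatch)),
            class = "mcsParams")
}

#' Maximum common substructure and overlap coefficient of two molecules
#'
#' Computes the heavy-atom size n of the maximum common connected
#' substructure of two molecular graphs and the overlap coefficient
#' n / min(c1, c2), where c1 and c2 are the molecules' heavy-atom counts.
#' The overlap coefficient is 1 whenever the smaller molecule is entirely
#' contained in the larger one, which makes it sensitive to local
#' similarity between molecules of very different size (its containment
#' bias). If the two molecules share no atom type at all the coefficient
#' is defined as 0 and a message is logged.
#'
#' The search is an exact branch-and-bound over connected common
#' subgraph mappings and is deterministic for fixed parameters. On
#' timeout, the best size found so far is returned and flagged.
#'
#' @param a,b molecular graphs (see \code{\link{compoundGraph}}).
#' @param params an \code{\link{mcsParams}} object.
#' @return an \linkS4class{McsResult}.
#' @examples
#' cs <- compoundsFromSmiles(c(eth = "CCO", prop = "CCCO"))
#' mcsOverlap(compoundGraph(cs, "eth"), compoundGraph(cs, "prop"))
#' @export
mcsOverlap <- function(a, b, params = mcsParams()) {
  c1 <- heavyAtomCount(a); c2 <- heavyAtomCount(b)
  if (c1 < 1 || c2 < 1) stop("molecule with 0 heavy atoms")
  swap <- c1 > c2
  ga <- if (swap) b else a
  gb <- if (swap) a else b
  if (params$connected) {
    res <- .mcsSearch(ga, gb, params)
  } else {
    ## greedy accumulation of connected components on the unmapped
    ## remainder; exact for the leading component, heuristic thereafter
    n <- 0L; timedOut <- FALSE
    keepA <- seq_along(ga$elements); keepB <- seq_along(gb$elements)
    repeat {
      if (!length(keepA) || !length(keepB)) break
      sub <- .mcsSearch(.subsetGraph(ga, keepA), .subsetGraph(gb, keepB),
                        params)
      timedOut <- timedOut || sub$timedOut
      if (sub$n == 0L) break
      n <- n + sub$n
      keepA <- keepA[-which(sub$map > 0L)]
      keepB <- keepB[-sub$map[sub$map > 0L]]
    }
    res <- list(n = n, timedOut = timedOut)
  }
  n <- res$n
  if (n == 0)
    message("molecules share no common atom; overlap coefficient set to 0")
  new("McsResult", n = as.integer(n), c1 = as.integer(c1),
      c2 = as.integer(c2),
      coefficient = n / min(c1, c2), timedOut = res$timedOut)
}

setMethod("show", "McsResult", function(object) {
  cat(sprintf("McsResult: n=%d  c1=%d  c2=%d  overlap=%.4f%s\n",
              object@n, object@c1, object@c2, object@coefficient,
              if (object@timedOut) "  [timed out: n is a lower bound]" else ""))
})

## ring-bond flags (bond participates in some cycle)
.ringBonds <- function(g) {
  nb <- nrow(g$bonds)
  flags <- rep(FALSE, nb)
  if (nb == 0) return(flags)
  ig <- igraph::graph_from_edgelist(cbind(g$bonds[, 1], g$bonds[, 2]),
                                    directed = FALSE)
  nAll <- length(g$elements)
  if (igraph::vcount(ig) < nAll)
    ig <- igraph::add_vertices(ig, nAll - igraph::vcount(ig))
  key <- paste(pmin(g$bonds[, 1], g$bonds[, 2]),
               pmax(g$bonds[, 1], g$bonds[, 2]))
  for (cyc in .fundamentalCycles(ig)) {
    pairs <- cbind(cyc, c(cyc[-1], cyc[1]))
    rk <- paste(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
    flags[match(rk, key)] <- TRUE
  }
  flags
}

## exact connected-MCS search; ga must not have more atoms than gb.
.mcsSearch <- function(ga, gb, params) {
  nA <- length(ga$elements); nB <- length(gb$elements)
  adjA <- .adjacency(ga); adjB <- .adjacency(gb)
  ringA <- .ringBonds(ga); ringB <- .ringBonds(gb)
  keyA <- new.env(); keyB <- new.env()   # bond -> ring flag lookup
  if (nrow(ga$bonds))
    for (k in seq_len(nrow(ga$bonds)))
      assign(paste(ga$bonds[k, 1], ga$bonds[k, 2]), ringA[k], envir = keyA)
  if (nrow(gb$bonds))
    for (k in seq_len(nrow(gb$bonds)))
      assign(paste(gb$bonds[k, 1], gb$bonds[k, 2]), ringB[k], envir = keyB)
  ringFlagA <- function(i, j) {
    v <- mget(paste(min(i, j), max(i, j)), envir = keyA,
              ifnotfound = list(FALSE))[[1]]
    v
  }
  ringFlagB <- function(i, j) {
    mget(paste(min(i, j), max(i, j)), envir = keyB,
         ifnotfound = list(FALSE))[[1]]
  }

  atomCompat <- function(i, j, budget) {
    okElem <- ga$elements[i] == gb$elements[j]
    okArom <- !params$matchAromatic || ga$aromatic[i] == gb$aromatic[j]
    if (okElem && okArom) return(0L)
    if (budget > 0L) return(1L)     # consume one atom-mismatch token
    NA_integer_
  }
  bondCompat <- function(orderA, orderB, budget) {
    if (!params$matchBondOrder || orderA == orderB) return(0L)
    if (budget > 0L) return(1L)
    NA_integer_
  }

  st <- new.env()
  st$best <- 0L
  st$bestMap <- integer(nA)
  st$timedOut <- FALSE
  st$nodes <- 0L
  deadline <- Sys.time() + params$timeout

  reachCount <- function(adj, seeds, blocked, total) {
    seen <- rep(FALSE, total); seen[seeds] <- TRUE
    frontier <- seeds
    cnt <- 0L
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        nb <- adj[[v]]
        if (nrow(nb) == 0) next
        for (w in nb[, 1]) {
          if (!seen[w] && !blocked[w]) {
            seen[w] <- TRUE; cnt <- cnt + 1L; nxt <- c(nxt, w)
          }
        }
      }
      frontier <- nxt
    }
    cnt
  }

  dfs <- function(mapA, mapB, excluded, abudget, bbudget) {
    st$nodes <- st$nodes + 1L
    if (st$nodes %% 64L == 0L && Sys.time() > deadline) {
      st$timedOut <- TRUE
      return(invisible())
    }
    size <- sum(mapA > 0L)
    if (size > st$best) { st$best <- size; st$bestMap <- mapA }
    mappedA <- which(mapA > 0L)
    blockedA <- excluded | mapA > 0L
    blockedB <- mapB > 0L
    bound <- size + min(reachCount(adjA, mappedA, blockedA, nA),
                        reachCount(adjB, mapA[mappedA], blockedB, nB))
    if (bound <= st$best) return(invisible())
    ## frontier: first non-excluded unmapped A atom adjacent to the map
    astar <- 0L
    for (u in mappedA) {
      nb <- adjA[[u]]
      if (nrow(nb) == 0) next
      for (w in nb[, 1])
        if (!blockedA[w] && (astar == 0L || w < astar)) astar <- w
    }
    if (astar == 0L) return(invisible())
    ## candidate images: unmapped B atoms adjacent (via a compatible bond)
    ## to the image of some mapped neighbor of astar
    tried <- integer(0)
    nbA <- adjA[[astar]]
    for (k in seq_len(nrow(nbA))) {
      u <- nbA[k, 1]
      if (mapA[u] == 0L) next
      ordA <- nbA[k, 2]
      bu <- mapA[u]
      nbB <- adjB[[bu]]
      if (nrow(nbB) == 0) next
      for (m in seq_len(nrow(nbB))) {
        bstar <- nbB[m, 1]
        if (mapB[bstar] > 0L || bstar %in% tried) next
        aCost <- atomCompat(astar, bstar, abudget)
        if (is.na(aCost)) next
        bCost <- bondCompat(ordA, nbB[m, 2], bbudget)
        if (is.na(bCost)) next
        if (params$ringMatchesRing &&
            ringFlagA(u, astar) != ringFlagB(bu, bstar)) next
        tried <- c(tried, bstar)
        mapA[astar] <- bstar; mapB[bstar] <- astar
        dfs(mapA, mapB, excluded, abudget - aCost, bbudget - bCost)
        mapA[astar] <- 0L; mapB[bstar] <- 0L
        if (st$timedOut) return(invisible())
      }
    }
    ## branch: exclude astar from this subtree
    excluded[astar] <- TRUE
    dfs(mapA, mapB, excluded, abudget, bbudget)
    invisible()
  }

  ## seed on each compatible atom pair; subgraphs through seed i exclude
  ## all A atoms < i, which makes the enumeration non-redundant
  for (i in seq_len(nA)) {
    if (st$best >= nA) break           # cannot do better
    for (j in seq_len(nB)) {
      if (st$timedOut) break
      aCost <- atomCompat(i, j, params$atomMismatch)
      if (is.na(aCost)) next
      mapA <- integer(nA); mapB <- integer(nB)
      mapA[i] <- j; mapB[j] <- i
      excluded <- rep(FALSE, nA)
      if (i > 1L) excluded[seq_len(i - 1L)] <- TRUE
      dfs(mapA, mapB, excluded, params$atomMismatch - aCost,
          params$bondMismatch)
    }
    if (st$timedOut) break
  }
  list(n = st$best, timedOut = st$timedOut, map = st$bestMap)
}

## atom-subset copy of a molecular graph (bonds remapped, no re-perception)
.subsetGraph <- function(g, keep) {
  idx <- integer(length(g$elements)); idx[keep] <- seq_along(keep)
  b <- g$bonds
  if (nrow(b)) {
    hh <- idx[b[, 1]] > 0 & idx[b[, 2]] > 0
    b <- b[hh, , drop = FALSE]
    if (nrow(b)) { b[, 1] <- idx[b[, 1]]; b[, 2] <- idx[b[, 2]] }
  }
  list(elements = g$elements[keep], aromatic = g$aromatic[keep],
       bonds = b)
}
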