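## Minimal heavy-atom molecular graph used by the MCS and fingerprint code.
## An object is a plain list:
##   elements : character, element symbol per heavy atom
##   aromatic : logical per atom
##   bonds    : numeric matrix, columns a1, a2, order (aromatic = 1.5)
## Hydrogens are stripped on construction; aromaticity is re-perceived from
## kekulized input (SDF writers emit alternating single/double bonds).

#' Construct a molecular graph
#'
#' Low-level constructor used by \code{\link{loadCompounds}} and the test
#' fixtures. Bonds are undirected; duplicate bonds are rejected.
#'
#' @param elements character vector of element symbols (heavy atoms only).
#' @param bonds numeric matrix or data.frame with columns a1, a2, order
#'   (1, 2, 3 or 1.5 for aromatic); may have zero rows.
#' @param aromatic optional logical per-atom flags; perceived from ring
#'   bond alternation when omitted.
#' @param perceiveAromatic re-perceive aromatic rings from kekulized bond
#'   orders (default TRUE).
#' @return a molecular graph list (elements, aromatic, bonds).
#' @export
molGraph <- function(elements, bonds = NULL, aromatic = NULL,
                     perceiveAromatic = TRUE) {
  elements <- as.character(elements)
  n <- length(elements)
  if (n < 1) stop("a molecule needs at least one heavy atom")
  if (is.null(bonds) || NROW(bonds) == 0) {
    bonds <- matrix(numeric(0), ncol = 3,
                    dimnames = list(NULL, c("a1", "a2", "order")))
  } else {
    bonds <- as.matrix(bonds)
    if (ncol(bonds) == 2) bonds <- cbind(bonds, 1)
    colnames(bonds) <- c("a1", "a2", "order")
    if (any(bonds[, 1:2] < 1 | bonds[, 1:2] > n))
      stop("bond endpoint out of range")
    if (any(bonds[, 1] == bonds[, 2])) stop("self-bonds are not allowed")
    key <- paste(pmin(bonds[, 1], bonds[, 2]), pmax(bonds[, 1], bonds[, 2]))
    if (anyDuplicated(key)) stop("duplicate bonds")
  }
  g <- list(elements = elements,
            aromatic = if (is.null(aromatic)) rep(FALSE, n)
                       else as.logical(aromatic),
            bonds = bonds)
  if (perceiveAromatic && is.null(aromatic)) g <- .perceiveAromatic(g)
  g
}

#' Heavy-atom count of a molecular graph
#' @param g a molecular graph.
#' @return integer number of heavy atoms.
#' @export
heavyAtomCount <- function(g) length(g$elements)

## adjacency list: for atom i, matrix with columns nbr, order
.adjacency <- function(g) {
  n <- length(g$elements)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- matrix(numeric(0), ncol = 2)
  b <- g$bonds
  for (k in seq_len(nrow(b))) {
    i <- b[k, 1]; j <- b[k, 2]; o <- b[k, 3]
    adj[[i]] <- rbind(adj[[i]], c(j, o))
    adj[[j]] <- rbind(adj[[j]], c(i, o))
  }
  adj
}

## connected components over a subset of atoms using only the given bonds
.isConnectedSubset <- function(subset, bonds) {
  if (length(subset) <= 1) return(TRUE)
  inset <- logical(max(subset)); inset[subset] <- TRUE
  keep <- bonds[, 1] <= length(inset) & bonds[, 2] <= length(inset)
  b <- bonds[keep & inset[bonds[, 1]] & inset[bonds[, 2]], , drop = FALSE]
  seen <- subset[1]; frontier <- subset[1]
  while (length(frontier)) {
    hit <- b[, 1] %in% frontier | b[, 2] %in% frontier
    nxt <- setdiff(unique(c(b[hit, 1], b[hit, 2])), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  length(seen) == length(subset)
}

## Re-perceive aromaticity from kekulized bond orders. Fundamental cycles
## come from a BFS spanning forest; a 5-7 ring of C/N/O/S atoms is marked
## aromatic when its in-ring pi-electron count satisfies the 4n+2 rule
## (each in-ring double bond contributes 2; an O/S/N with no in-ring double
## bond contributes a lone pair). Isolated benzene-like rings, pyridines,
## furans and thiophenes are recovered; fused aromatics are a documented
## limitation of the ring-local rule.
.perceiveAromatic <- function(g) {
  b <- g$bonds
  if (nrow(b) == 0) return(g)
  n <- length(g$elements)
  ig <- igraph::graph_from_edgelist(cbind(b[, 1], b[, 2]), directed = FALSE)
  if (igraph::vcount(ig) < n) ig <- igraph::add_vertices(ig, n - igraph::vcount(ig))
  cycles <- .fundamentalCycles(ig)
  bondKey <- paste(pmin(b[, 1], b[, 2]), pmax(b[, 1], b[, 2]))
  aromAtoms <- rep(FALSE, n)
  aromBonds <- rep(FALSE, nrow(b))
  for (cyc in cycles) {
    L <- length(cyc)
    if (L < 5 || L > 7) next
    if (!all(g$elements[cyc] %in% c("C", "N", "O", "S"))) next
    ringPairs <- cbind(cyc, c(cyc[-1], cyc[1]))
    rk <- paste(pmin(ringPairs[, 1], ringPairs[, 2]),
                pmax(ringPairs[, 1], ringPairs[, 2]))
    idx <- match(rk, bondKey)
    if (anyNA(idx)) next
    orders <- b[idx, 3]
    if (any(orders > 2)) next
    nDouble <- sum(orders == 2)
    ## atoms incident to an in-ring double bond
    dblAtoms <- unique(c(ringPairs[orders == 2, ]))
    lonePair <- sum(g$elements[cyc] %in% c("N", "O", "S") &
                    !(cyc %in% dblAtoms))
    pi <- 2 * nDouble + 2 * lonePair
    if (pi %% 4 == 2) {
      aromAtoms[cyc] <- TRUE
      aromBonds[idx] <- TRUE
    }
  }
  g$aromatic <- g$aromatic | aromAtoms
  g$bonds[aromBonds, 3] <- 1.5
  g
}

## fundamental cycle basis of an undirected igraph via a BFS forest
.fundamentalCycles <- function(ig) {
  n <- igraph::vcount(ig)
  parent <- rep(NA_integer_, n)
  depth <- rep(NA_integer_, n)
  for (root in seq_len(n)) {
    if (!is.na(depth[root])) next
    depth[root] <- 0L
    queue <- root
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in as.integer(igraph::neighbors(ig, v))) {
        if (is.na(depth[w])) {
          depth[w] <- depth[v] + 1L
          parent[w] <- v
          queue <- c(queue, w)
        }
      }
    }
  }
  el <- igraph::as_edgelist(ig, names = FALSE)
  treeKey <- paste(pmin(seq_len(n), parent), pmax(seq_len(n), parent))
  treeKey <- treeKey[!is.na(parent)]
  cycles <- list()
  for (k in seq_len(nrow(el))) {
    u <- el[k, 1]; v <- el[k, 2]
    if (paste(min(u, v), max(u, v)) %in% treeKey) next
    ## path to common ancestor
    pu <- u; pv <- v
    au <- u; av <- v
    while (!is.na(depth[au]) && !is.na(depth[av]) && au != av) {
      if (depth[au] >= depth[av]) { au <- parent[au]; pu <- c(pu, au) }
      else { av <- parent[av]; pv <- c(pv, av) }
      if (is.na(au) || is.na(av)) break
    }
    if (is.na(au) || is.na(av) || au != av) next
    cyc <- c(pu, rev(pv[-length(pv)]))
    cycles[[length(cycles) + 1L]] <- cyc
  }
  cycles
}

## Build a molecular graph from one ChemmineR SDF object: strip explicit
## hydrogens, translate bond order 4 (aromatic SDF convention) to 1.5.
.graphFromSDF <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  if (!all(grepl("^[A-Za-z]{1,2}_[0-9]+$", rownames(ab))))
    stop("unparseable atom block")   # bond-less records; see .graphFromMolblock
  elements <- sub("_.*$", "", rownames(ab))
  keep <- elements != "H"
  idx <- cumsum(keep)      # old index -> new index (valid where keep)
  bonds <- NULL
  if (NROW(bb) > 0) {
    b <- cbind(as.numeric(bb[, 1]), as.numeric(bb[, 2]), as.numeric(bb[, 3]))
    hh <- keep[b[, 1]] & keep[b[, 2]]
    b <- b[hh, , drop = FALSE]
    if (nrow(b)) {
      b[, 1] <- idx[b[, 1]]
      b[, 2] <- idx[b[, 2]]
      b[b[, 3] == 4, 3] <- 1.5
      bonds <- b
    }
  }
  molGraph(elements[keep], bonds)
}

## Direct V2000 molblock parse, used for records the SDF container class
## rejects (molecules without bonds are flagged invalid there).
.graphFromMolblock <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  counts <- grep(" V2000\\s*$", lines)[1]
  if (is.na(counts)) stop("no V2000 counts line")
  natoms <- as.integer(substr(lines[counts], 1, 3))
  nbonds <- as.integer(substr(lines[counts], 4, 6))
  atomLines <- lines[counts + seq_len(natoms)]
  elements <- vapply(strsplit(trimws(atomLines), "[ \t]+"), `[`,
                     character(1), 4)
  bonds <- NULL
  if (nbonds > 0) {
    bl <- lines[counts + natoms + seq_len(nbonds)]
    bonds <- cbind(as.numeric(substr(bl, 1, 3)),
                   as.numeric(substr(bl, 4, 6)),
                   as.numeric(substr(bl, 7, 9)))
  }
  keep <- elements != "H"
  idx <- cumsum(keep)
  if (!is.null(bonds)) {
    hh <- keep[bonds[, 1]] & keep[bonds[, 2]]
    bonds <- bonds[hh, , drop = FALSE]
    if (nrow(bonds)) {
      bonds[, 1] <- idx[bonds[, 1]]
      bonds[, 2] <- idx[bonds[, 2]]
      bonds[bonds[, 3] == 4, 3] <- 1.5
    } else bonds <- NULL
  }
  molGraph(elements[keep], bonds)
}
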