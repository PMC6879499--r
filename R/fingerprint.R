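#' Hashed circular (Morgan-style) fingerprint of a molecule
#'
#' Encodes topological atom neighbourhoods: every atom starts from an
#' invariant built from its element, degree, aromaticity and incident
#' bond orders, and the invariant is iteratively re-hashed together with
#' the sorted (bond order, neighbour invariant) pairs out to the given
#' radius. All invariants from radius 0 up to \code{radius} are folded
#' into an \code{nBits}-bit set. The hash is a deterministic integer
#' polynomial, so fingerprints are identical across platforms and runs
#' (bit positions are not interchangeable with other ECFP software).
#'
#' @param g a molecular graph.
#' @param radius neighbourhood radius (default 2, the ECFP4 equivalent).
#' @param nBits fingerprint length, a power of two (default 2048).
#' @return sorted integer vector of set bit positions in [0, nBits).
#' @export
morganFingerprint <- function(g, radius = 2L, nBits = 2048L) {
  if (radius < 1) stop("radius must be >= 1")
  if (nBits < 2 || bitwAnd(nBits, nBits - 1L) != 0)
    stop("nBits must be a power of two")
  n <- heavyAtomCount(g)
  if (n < 1) stop("molecule with 0 heavy atoms")
  adj <- .adjacency(g)
  degree <- vapply(adj, nrow, integer(1))
  inv <- vapply(seq_len(n), function(i) {
    orders <- sort(adj[[i]][, 2] * 10)
    .hashChain(c(match(g$elements[i], .elementTable(), nomatch = 999L),
                 degree[i], as.integer(g$aromatic[i]), orders))
  }, numeric(1))
  feats <- inv
  for (r in seq_len(radius)) {
    inv <- vapply(seq_len(n), function(i) {
      nb <- adj[[i]]
      pieces <- if (nrow(nb) == 0) numeric(0) else {
        ord <- order(nb[, 2] * 1e10 + inv[nb[, 1]])
        as.numeric(t(cbind(nb[ord, 2] * 10, inv[nb[ord, 1]])))
      }
      .hashChain(c(r, inv[i], pieces))
    }, numeric(1))
    feats <- c(feats, inv)
  }
  sort(unique(as.integer(feats %% nBits)))
}

.elementTable <- function()
  c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "B", "Si", "Se", "H")

## deterministic polynomial rolling hash over non-negative numbers,
## exact in double arithmetic (modulus < 2^31, multiplier kept small)
.hashChain <- function(x) {
  h <- 17
  for (v in x) h <- (h * 31 + (v %% 2147483647)) %% 2147483647
  h
}

#' Tanimoto coefficient of two bit sets
#'
#' |A intersect B| / |A union B|; 1 when both sets are empty.
#'
#' @param a,b integer vectors of set bit positions.
#' @return numeric in [0, 1].
#' @examples
#' tanimotoCoefficient(c(1, 2, 3), c(2, 3, 4))  # 2/4 = 0.5
#' @export
tanimotoCoefficient <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) return(1)
  length(intersect(a, b)) / u
}

#' Morgan-fingerprint Tanimoto similarity of two molecules
#'
#' @param a,b molecular graphs.
#' @param radius,nBits see \code{\link{morganFingerprint}}.
#' @return Tanimoto similarity in [0, 1].
#' @export
morganTanimoto <- function(a, b, radius = 2L, nBits = 2048L) {
  tanimotoCoefficient(morganFingerprint(a, radius, nBits),
                      morganFingerprint(b, radius, nBits))
}
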