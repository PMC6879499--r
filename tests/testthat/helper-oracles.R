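# Independent brute-force oracles and shared fixtures.

# Ten small molecules (all <= 8 heavy atoms) used for exhaustive
# MCS-vs-oracle comparison.
smallMoleculeSmiles <- c(
  methane = "C", ethanol = "CCO", propanol = "CCCO",
  acetic = "CC(=O)O", ethylamine = "CCN", benzene = "c1ccccc1",
  cyclohexane = "C1CCCCC1", isopropanol = "CC(C)O", ether = "CCOC",
  toluene = "Cc1ccccc1")

smallMoleculeSet <- function() compoundsFromSmiles(smallMoleculeSmiles)

# Exhaustive maximum-common-connected-substructure size oracle.
# Enumerates connected atom subsets S of the smaller molecule from the
# largest size down; for each S tries every injective element-preserving
# assignment into the other molecule and accepts when the bonds shared by
# both molecules under the assignment (equal order) connect all of S.
# Completely independent of the package's branch-and-bound search.
mcsBruteSize <- function(ga, gb) {
  if (length(ga$elements) > length(gb$elements)) {
    tmp <- ga; ga <- gb; gb <- tmp
  }
  nA <- length(ga$elements); nB <- length(gb$elements)
  bondOrder <- function(bonds, i, j) {
    if (nrow(bonds) == 0) return(NA_real_)
    hit <- (bonds[, 1] == i & bonds[, 2] == j) |
           (bonds[, 1] == j & bonds[, 2] == i)
    if (any(hit)) bonds[which(hit)[1], 3] else NA_real_
  }
  connectedInA <- function(S) {
    if (length(S) == 1) return(TRUE)
    seen <- S[1]
    repeat {
      grew <- FALSE
      for (x in setdiff(S, seen)) {
        if (any(!is.na(vapply(seen, function(y)
          bondOrder(ga$bonds, x, y), numeric(1))))) {
          seen <- c(seen, x); grew <- TRUE
        }
      }
      if (!grew) break
    }
    length(seen) == length(S)
  }
  sharedConnected <- function(S, img) {
    k <- length(S)
    if (k == 1) return(TRUE)
    seen <- 1L
    repeat {
      grew <- FALSE
      for (p in setdiff(seq_len(k), seen)) {
        for (q in seen) {
          oa <- bondOrder(ga$bonds, S[p], S[q])
          ob <- bondOrder(gb$bonds, img[p], img[q])
          if (!is.na(oa) && !is.na(ob) && oa == ob) {
            seen <- c(seen, p); grew <- TRUE; break
          }
        }
      }
      if (!grew) break
    }
    length(seen) == k
  }
  embeds <- function(S) {
    k <- length(S)
    used <- rep(FALSE, nB)
    img <- integer(k)
    rec <- function(pos) {
      if (pos > k) return(sharedConnected(S, img))
      for (b in seq_len(nB)) {
        if (used[b] || gb$elements[b] != ga$elements[S[pos]]) next
        used[b] <<- TRUE; img[pos] <<- b
        if (rec(pos + 1)) { used[b] <<- FALSE; return(TRUE) }
        used[b] <<- FALSE
      }
      FALSE
    }
    rec(1)
  }
  allSubsets <- lapply(seq_len(2^nA - 1), function(mask)
    which(bitwAnd(mask, 2^(seq_len(nA) - 1)) > 0))
  conn <- Filter(connectedInA, allSubsets)
  sizes <- vapply(conn, length, integer(1))
  for (k in sort(unique(sizes), decreasing = TRUE)) {
    for (S in conn[sizes == k]) if (embeds(S)) return(k)
  }
  0L
}

# Adjusted Rand index straight from the contingency-table formula.
ariBrute <- function(p1, p2) {
  tab <- table(p1, p2)
  n <- sum(tab)
  ch2 <- function(x) x * (x - 1) / 2
  sumIj <- sum(ch2(tab))
  sumI <- sum(ch2(rowSums(tab)))
  sumJ <- sum(ch2(colSums(tab)))
  expected <- sumI * sumJ / ch2(n)
  (sumIj - expected) / ((sumI + sumJ) / 2 - expected)
}

# Two planted feature blocks with mirrored profiles (means +/-5, sd 1):
# the first half of the items load positively on the first half of the
# features, the second half mirrored, so the two blocks are perfectly
# anticorrelated up to noise.
plantedBlockFeatures <- function(nItems = 12, nFeatures = 50, seed = 1) {
  set.seed(seed)
  half <- nItems / 2
  pattern <- c(rep(5, nFeatures / 2), rep(-5, nFeatures - nFeatures / 2))
  f <- rbind(
    matrix(rep(pattern, each = half), half) + rnorm(half * nFeatures),
    matrix(rep(-pattern, each = nItems - half), nItems - half) +
      rnorm((nItems - half) * nFeatures))
  rownames(f) <- sprintf("it%02d", seq_len(nItems))
  f
}

randomScoreMatrix <- function(nc, np, naFrac = 0) {
  m <- matrix(runif(nc * np, 0, 10), nc, np,
              dimnames = list(sprintf("c%02d", seq_len(nc)),
                              sprintf("p%02d", seq_len(np))))
  if (naFrac > 0) m[sample(length(m), round(naFrac * length(m)))] <- NA
  m
}
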