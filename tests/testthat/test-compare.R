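toyTree <- function(d, labels) {
  m <- as.matrix(d)
  dimnames(m) <- list(labels, labels)
  hierarchicalCluster(new("DissimilarityMatrix", m))
}

test_that("a tree compared with itself is perfect agreement at every k", {
  set.seed(21)
  f <- matrix(rnorm(6 * 12), 6, dimnames = list(letters[1:6], NULL))
  hc <- hierarchicalCluster(correlationDissimilarity(f))
  for (k in 2:6) {
    rec <- compareTrees(hc, hc, k)
    expect_equal(rec$adjustedRand, 1)
    expect_equal(rec$fowlkesMallows, 1)
    expect_equal(rec$copheneticCorrelation, 1)
  }
})

test_that("crossed partitions {AB|CD} vs {AC|BD} score non-positive ARI", {
  ## trees built so the k=2 cut gives exactly those partitions
  m1 <- matrix(1, 4, 4); diag(m1) <- 0
  m1[1, 2] <- m1[2, 1] <- 0.1; m1[3, 4] <- m1[4, 3] <- 0.1
  m2 <- matrix(1, 4, 4); diag(m2) <- 0
  m2[1, 3] <- m2[3, 1] <- 0.1; m2[2, 4] <- m2[4, 2] <- 0.1
  lab <- c("A", "B", "C", "D")
  t1 <- toyTree(m1, lab); t2 <- toyTree(m2, lab)
  rec <- compareTrees(t1, t2, 2)
  expect_lte(rec$adjustedRand, 0)
  ## cross-check against the contingency-table formula
  p1 <- stats::cutree(t1, 2)[lab]
  p2 <- stats::cutree(t2, 2)[lab]
  expect_equal(rec$adjustedRand, ariBrute(p1, p2))
  ## no pair co-clusters in both partitions, so Fowlkes-Mallows is 0
  expect_equal(rec$fowlkesMallows, 0)
})

test_that("ARI matches the brute-force contingency formula on random partitions", {
  set.seed(33)
  for (rep in 1:25) {
    n <- sample(6:15, 1)
    p1 <- sample(1:3, n, replace = TRUE)
    p2 <- sample(1:3, n, replace = TRUE)
    expect_equal(mclust::adjustedRandIndex(p1, p2), ariBrute(p1, p2))
  }
})

test_that("independent random trees have ARI near zero on average", {
  set.seed(8)
  aris <- replicate(30, {
    f1 <- matrix(rnorm(12 * 20), 12,
                 dimnames = list(sprintf("c%02d", 1:12), NULL))
    f2 <- matrix(rnorm(12 * 20), 12,
                 dimnames = list(sprintf("c%02d", 1:12), NULL))
    compareTrees(hierarchicalCluster(correlationDissimilarity(f1)),
                 hierarchicalCluster(correlationDissimilarity(f2)),
                 k = 3)$adjustedRand
  })
  expect_lt(abs(mean(aris)), 0.15)
})

test_that("leaf-set mismatches and bad k are rejected", {
  f <- matrix(rnorm(4 * 10), 4, dimnames = list(letters[1:4], NULL))
  g <- matrix(rnorm(4 * 10), 4, dimnames = list(letters[3:6], NULL))
  ta <- hierarchicalCluster(correlationDissimilarity(f))
  tb <- hierarchicalCluster(correlationDissimilarity(g))
  expect_error(compareTrees(ta, tb, 2), "leaf sets differ.*[aef]")
  expect_error(compareTrees(ta, ta, 1), "k must satisfy")
  expect_error(compareTrees(ta, ta, 5), "k must satisfy")
})

test_that("Newick export follows the ultrametric halving convention", {
  m <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("A", "B"),
                                                    c("A", "B")))
  hc <- hierarchicalCluster(new("DissimilarityMatrix", m))
  expect_equal(toNewick(hc), "(A:0.2,B:0.2);")
})

test_that("Newick round-trips topology and carries AU labels", {
  skip_if_not_installed("ape")
  f <- plantedBlockFeatures(8, 30, seed = 7)
  cl <- multiscaleBootstrap(f, nboot = 50, seed = 3)
  nwk <- toNewick(cl)
  ph <- ape::read.tree(text = nwk)
  expect_setequal(ph$tip.label, cl@tree$labels)
  labs <- suppressWarnings(as.numeric(ph$node.label))
  labs <- labs[!is.na(labs)]
  expect_true(length(labs) >= 1)
  expect_true(all(labs >= 0 & labs <= 1))
  ## cophenetic distances of the parsed tree match the hclust ones
  co1 <- as.matrix(stats::cophenetic(cl@tree))
  co2 <- ape::cophenetic.phylo(ph)[rownames(co1), colnames(co1)]
  expect_equal(unname(co2), unname(co1), tolerance = 1e-6)
})
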