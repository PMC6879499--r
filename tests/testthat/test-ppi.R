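writeStringTsv <- function(rows, path) {
  writeLines(c("protein1\tprotein2\tcombined_score", rows), path)
}

test_that("STRING exports are confidence-filtered at 0.7 by default", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeStringTsv(c("A\tB\t900", "B\tC\t400"), f)
  g <- suppressMessages(readPPI(f, "string_tsv"))
  expect_equal(igraph::ecount(g), 1)
  expect_setequal(igraph::as_edgelist(g)[1, ], c("A", "B"))
  expect_equal(igraph::E(g)$confidence, 0.9)
  ## lowering the threshold keeps the weak edge; raising never adds edges
  g2 <- suppressMessages(readPPI(f, "string_tsv", minConfidence = 0.3))
  expect_equal(igraph::ecount(g2), 2)
  for (thr in c(0.5, 0.8, 0.95)) {
    expect_lte(igraph::ecount(suppressMessages(
      readPPI(f, "string_tsv", minConfidence = thr))),
      igraph::ecount(suppressMessages(
        readPPI(f, "string_tsv", minConfidence = thr - 0.2))))
  }
})

test_that("duplicate edges and self-loops are removed, nodes retained", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeStringTsv(c("A\tB\t900", "B\tA\t900"), f)
  g <- suppressMessages(readPPI(f, "string_tsv"))
  expect_equal(igraph::ecount(g), 1)
  writeStringTsv("A\tA\t990", f)
  g2 <- suppressMessages(readPPI(f, "string_tsv"))
  expect_equal(igraph::ecount(g2), 0)
  expect_identical(igraph::V(g2)$name, "A")
})

test_that("SIF and two-column formats parse; malformed lines skip or abort", {
  f <- withr::local_tempfile(fileext = ".sif")
  writeLines(c("A pp B C", "D pp E", "lonely", "bad-line B"), f)
  expect_warning(g <- readPPI(f, "sif"), "malformed")
  expect_equal(igraph::ecount(g), 3)      # A-B, A-C, D-E
  expect_true("lonely" %in% igraph::V(g)$name)
  expect_error(suppressWarnings(readPPI(f, "sif", strict = TRUE)),
               "malformed")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "B\tC"), f2)
  g2 <- readPPI(f2, "tsv2col")
  expect_equal(igraph::ecount(g2), 2)
  expect_error(readPPI(f2, "nonsense"), "arg")
})

test_that("node file adds isolated proteins with degree zero", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeStringTsv("A\tB\t800", f)
  nf <- withr::local_tempfile()
  writeLines(c("A", "Z"), nf)
  g <- suppressMessages(readPPI(f, "string_tsv", nodeFile = nf))
  d <- nodeDegrees(g)
  expect_equal(unname(d["Z"]), 0L)
  expect_equal(unname(d["A"]), 1L)
})

test_that("node degrees match hand-built topologies", {
  tri <- igraph::make_graph(~ A - B, B - C, C - A)
  expect_equal(unname(nodeDegrees(tri)[c("A", "B", "C")]), c(2L, 2L, 2L))
  star <- igraph::make_star(5, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("H", paste0("L", 1:4))
  d <- nodeDegrees(star)
  expect_equal(unname(d["H"]), 4L)
  expect_true(all(d[paste0("L", 1:4)] == 1L))
  empty <- igraph::make_empty_graph(0, directed = FALSE)
  expect_length(nodeDegrees(empty), 0)
})

test_that("the handshake lemma holds on random graphs", {
  set.seed(5)
  for (rep in 1:20) {
    g <- igraph::sample_gnp(sample(5:40, 1), runif(1, 0.05, 0.5))
    expect_equal(sum(nodeDegrees(g)), 2 * igraph::ecount(g))
    expect_true(all(nodeDegrees(g) <= igraph::vcount(g) - 1))
  }
})

test_that("network effect is the elementwise rank x degree product", {
  ranks <- new("RankMatrix",
               matrix(c(1, 2, 2, 1), 2, 2, byrow = TRUE,
                      dimnames = list(c("a", "b"), c("p1", "p2"))))
  eff <- networkEffect(ranks, c(p1 = 3, p2 = 1))
  expect_equal(unname(eff@.Data), matrix(c(3, 2, 6, 1), 2, byrow = TRUE))
  ## a docking rank of 2.5 on a hub of degree 55 (the mTOR row of the
  ## packaged degree table) contributes 137.5
  deg <- ageingFixture()$degrees
  r <- new("RankMatrix",
           matrix(c(2.5, 2.5, 1, 4,
                    1, 2, 3, 4), 2, 4, byrow = TRUE,
                  dimnames = list(c("a", "b"),
                                  c("mTOR", "PDE4B", "AKT", "AMPK"))))
  e <- networkEffect(r, deg)
  expect_equal(e@.Data["a", "mTOR"], 137.5)
  ## degree 0 wipes the column
  e0 <- networkEffect(ranks, c(p1 = 0, p2 = 2))
  expect_true(all(e0@.Data[, "p1"] == 0))
})

test_that("network effect agrees with an explicit double loop and scales linearly", {
  set.seed(9)
  for (rep in 1:20) {
    nc <- sample(3:8, 1); np <- sample(3:10, 1)
    r <- rankNormalize(new("DockingScoreMatrix",
                           randomScoreMatrix(nc, np)))
    deg <- stats::setNames(sample(0:50, np, replace = TRUE),
                           colnames(r@.Data))
    eff <- networkEffect(r, deg)@.Data
    manual <- eff
    for (i in seq_len(nc)) for (j in seq_len(np))
      manual[i, j] <- r@.Data[i, j] * deg[colnames(r@.Data)[j]]
    expect_equal(eff, manual)
    expect_equal(networkEffect(r, 3 * deg)@.Data, 3 * eff)
  }
})

test_that("missing-protein policies behave as declared", {
  ranks <- new("RankMatrix",
               matrix(c(1, 2, 2, 1), 2, 2, byrow = TRUE,
                      dimnames = list(c("a", "b"), c("p1", "px"))))
  deg <- c(p1 = 4)
  zero <- suppressMessages(networkEffect(ranks, deg, "zero"))
  expect_true(all(zero@.Data[, "px"] == 0))
  drop <- suppressMessages(networkEffect(ranks, deg, "drop"))
  expect_identical(proteinIds(drop), "p1")
  expect_error(suppressMessages(networkEffect(ranks, deg, "error")), "px")
  expect_error(networkEffect(ranks, c(q1 = 1)), "no rank proteins")
})

test_that("degree table and SIF writers round-trip", {
  g <- igraph::make_graph(~ A - B, B - C)
  f <- withr::local_tempfile(fileext = ".csv")
  writeDegreeTable(nodeDegrees(g), f)
  back <- utils::read.csv(f)
  expect_equal(stats::setNames(back$degree, back$protein),
               c(A = 1L, B = 2L, C = 1L))
  sf <- withr::local_tempfile(fileext = ".sif")
  writeSif(g, sf)
  g2 <- readPPI(sf, "sif")
  expect_equal(igraph::ecount(g2), 2)
})
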