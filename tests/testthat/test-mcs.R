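test_that("overlap coefficient is 1 for self-comparison", {
  cs <- smallMoleculeSet()
  for (id in c("methane", "ethanol", "benzene", "toluene")) {
    r <- mcsOverlap(compoundGraph(cs, id), compoundGraph(cs, id))
    expect_equal(r@coefficient, 1.0)
    expect_equal(r@n, heavyAtomCount(compoundGraph(cs, id)))
    expect_false(r@timedOut)
  }
})

test_that("containment gives coefficient 1 (ethanol in propanol, methane in ethanol)", {
  cs <- smallMoleculeSet()
  r <- mcsOverlap(compoundGraph(cs, "ethanol"), compoundGraph(cs, "propanol"))
  expect_equal(r@n, 3L)
  expect_equal(r@c1, 3L)
  expect_equal(r@c2, 4L)
  expect_equal(r@coefficient, 1.0)
  ## the overlap coefficient's containment bias: a single shared atom
  ## saturates the coefficient when the smaller molecule is one atom
  r2 <- mcsOverlap(compoundGraph(cs, "methane"), compoundGraph(cs, "ethanol"))
  expect_equal(r2@n, 1L)
  expect_equal(min(r2@c1, r2@c2), 1L)
  expect_equal(r2@coefficient, 1.0)
})

test_that("MCS result is symmetric under argument swap", {
  cs <- smallMoleculeSet()
  ids <- compoundIds(cs)
  pairs <- utils::combn(ids, 2)
  for (p in sample(ncol(pairs), 10)) {
    a <- compoundGraph(cs, pairs[1, p]); b <- compoundGraph(cs, pairs[2, p])
    r1 <- mcsOverlap(a, b); r2 <- mcsOverlap(b, a)
    expect_equal(r1@n, r2@n)
    expect_equal(r1@coefficient, r2@coefficient)
    expect_equal(r1@c1, r2@c2)
  }
})

test_that("search agrees with the exhaustive enumerator on spot-checked pairs", {
  cs <- smallMoleculeSet()
  pairs <- list(c("ethanol", "propanol"), c("benzene", "toluene"),
                c("cyclohexane", "toluene"), c("acetic", "isopropanol"),
                c("ether", "propanol"))
  for (p in pairs) {
    a <- compoundGraph(cs, p[1]); b <- compoundGraph(cs, p[2])
    expect_equal(mcsOverlap(a, b)@n, mcsBruteSize(a, b),
                 info = paste(p, collapse = " vs "))
  }
})

test_that("disjoint element sets give coefficient 0 with a log message", {
  a <- molGraph("C")
  b <- molGraph(c("N", "O"), cbind(1, 2, 1))
  expect_message(r <- mcsOverlap(a, b), "no common atom")
  expect_equal(r@n, 0L)
  expect_equal(r@coefficient, 0)
})

test_that("an aromatic ring does not map onto an aliphatic ring", {
  cs <- smallMoleculeSet()
  r <- mcsOverlap(compoundGraph(cs, "benzene"),
                  compoundGraph(cs, "cyclohexane"))
  expect_equal(r@n, 1L)   # atoms share the element, no bond matches
  ## relaxing bond-order matching recovers the full ring
  r2 <- mcsOverlap(compoundGraph(cs, "benzene"),
                   compoundGraph(cs, "cyclohexane"),
                   mcsParams(matchBondOrder = FALSE))
  expect_equal(r2@n, 6L)
})

test_that("mismatch budgets extend the common substructure", {
  cs <- compoundsFromSmiles(c(a = "CCCO", b = "CCCN"))
  strict <- mcsOverlap(compoundGraph(cs, "a"), compoundGraph(cs, "b"))
  expect_equal(strict@n, 3L)             # the shared CCC chain
  relaxed <- mcsOverlap(compoundGraph(cs, "a"), compoundGraph(cs, "b"),
                        mcsParams(atomMismatch = 1))
  expect_equal(relaxed@n, 4L)            # O ~ N tolerated once
})

test_that("timeout returns the best-so-far size with a flag", {
  cs <- compoundsFromSmiles(
    c(a = "CC(C)(C)CC(C)(C)CC(C)(C)CC(C)(C)C", b = strrep("C", 16)))
  r <- mcsOverlap(compoundGraph(cs, "a"), compoundGraph(cs, "b"),
                  mcsParams(timeout = 0))
  expect_true(r@timedOut)
  expect_gte(r@n, 1L)
  expect_lte(r@n, 16L)
})

test_that("zero-heavy-atom input is a domain error", {
  expect_error(molGraph(character(0)), "at least one heavy atom")
})

test_that("similarity matrices are symmetric with unit diagonal, in set order", {
  cs <- compoundsFromSmiles(c(e = "CCO", p = "CCCO", m = "C"))
  sm <- similarityMatrix(cs, "mcs_overlap")
  expect_identical(compoundIds(sm), c("e", "p", "m"))
  expect_equal(diag(sm@.Data), stats::setNames(rep(1, 3), c("e", "p", "m")))
  ## every pair here is a containment pair
  expect_true(all(sm@.Data == 1))
  sm2 <- similarityMatrix(cs, "mcs_overlap")
  expect_identical(sm@.Data, sm2@.Data)   # deterministic
})

test_that("similarity CSV round-trips exactly", {
  cs <- smallMoleculeSet()[c("ethanol", "propanol", "benzene", "toluene")]
  sm <- similarityMatrix(cs, "morgan_tanimoto")
  f <- withr::local_tempfile(fileext = ".csv")
  writeSimilarityCsv(sm, f)
  back <- readSimilarityCsv(f, method = "morgan_tanimoto")
  expect_identical(back@.Data, sm@.Data)
})
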