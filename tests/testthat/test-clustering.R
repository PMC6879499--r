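test_that("correlation dissimilarity has its closed-form values", {
  f <- rbind(a = c(1, 2, 3), b = c(2, 4, 6), c = c(3, 2, 1))
  d <- correlationDissimilarity(f)
  expect_s4_class(d, "DissimilarityMatrix")
  expect_equal(d@.Data["a", "b"], 0)       # identical up to scaling
  expect_equal(d@.Data["a", "c"], 2)       # exactly anticorrelated
  expect_equal(diag(d@.Data), c(a = 0, b = 0, c = 0))
})

test_that("degenerate feature inputs are rejected with names", {
  f <- rbind(a = c(1, 2, 3), flat = c(2, 2, 2))
  expect_error(correlationDissimilarity(f), "flat")
  expect_error(correlationDissimilarity(f[1, , drop = FALSE]),
               "at least 2 items")
  expect_error(correlationDissimilarity(f[, 1:2]), "3 features")
  expect_error(correlationDissimilarity(unname(f)), "row names")
})

test_that("average-linkage agglomeration is exact on a 3-item toy case", {
  m <- matrix(c(0, 0.1, 0.9,
                0.1, 0, 0.9,
                0.9, 0.9, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  hc <- hierarchicalCluster(new("DissimilarityMatrix", m))
  expect_equal(hc$height, c(0.1, 0.9))
  first <- sort(hc$labels[-hc$merge[1, ]])
  expect_identical(first, c("A", "B"))
  ## two items: single merge at their distance
  hc2 <- hierarchicalCluster(new("DissimilarityMatrix", m[1:2, 1:2]))
  expect_equal(hc2$height, 0.1)
  ## determinism
  expect_identical(hierarchicalCluster(new("DissimilarityMatrix", m)),
                   hc)
  expect_error(hierarchicalCluster(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("probit fit recovers the analytic anchors", {
  sc <- seq(0.5, 1.4, by = 0.1)
  flat <- fitScalingCurve(rep(0.5, 10), sc, 1000)
  expect_equal(flat$au, 0.5)
  expect_equal(flat$v, 0, tolerance = 1e-12)
  expect_equal(flat$c, 0, tolerance = 1e-12)
  hi <- fitScalingCurve(rep(1, 10), sc, 1000)
  expect_true(hi$degenerate)
  expect_equal(hi$au, 1)
  lo <- fitScalingCurve(rep(0, 10), sc, 1000)
  expect_equal(lo$au, 0)
  single <- fitScalingCurve(0.73, 1, 1000)
  expect_equal(single$au, 0.73, tolerance = 1e-3)   # classical bootstrap
  expect_equal(single$bp, single$au)
})

test_that("multiscale bootstrap is seed-deterministic with bounded support", {
  set.seed(2)
  f <- matrix(rnorm(8 * 20), 8,
              dimnames = list(paste0("it", 1:8), NULL))
  c1 <- multiscaleBootstrap(f, nboot = 50, seed = 99)
  c2 <- multiscaleBootstrap(f, nboot = 50, seed = 99)
  expect_identical(supportTable(c1), supportTable(c2))
  expect_identical(c1@support@counts, c2@support@counts)
  t <- supportTable(c1)
  expect_true(all(t$au >= 0 & t$au <= 1))
  expect_true(all(t$bp >= 0 & t$bp <= 1))
  ## root cluster carries support 1 by convention
  root <- t[nchar(t$members) == max(nchar(t$members)), ]
  expect_equal(root$au, 1)
  ## counts never exceed the replicate budget
  for (cnt in c1@support@counts)
    expect_true(all(cnt["hits", ] <= cnt["nboot", ]))
  ## average-linkage heights are monotone non-decreasing
  expect_true(all(diff(c1@tree$height) >= -1e-12))
})

test_that("a resampling scale below 3 features is rejected", {
  f <- matrix(rnorm(4 * 5), 4, dimnames = list(letters[1:4], NULL))
  expect_error(multiscaleBootstrap(f, scales = c(0.2, 1), nboot = 10,
                                   seed = 1), "< 3 features")
  expect_error(multiscaleBootstrap(f, nboot = 10), "seed is mandatory")
})

test_that("single-scale mode reduces to the classical bootstrap", {
  f <- plantedBlockFeatures(8, 30, seed = 4) +
    matrix(rnorm(8 * 30, sd = 3), 8)    # noisy enough for mid-range BP
  cl <- multiscaleBootstrap(f, scales = 1, nboot = 200, seed = 5)
  t <- supportTable(cl)
  nonRoot <- t[t$members != t$members[which.max(nchar(t$members))], ]
  se <- sqrt(pmax(nonRoot$bpRaw * (1 - nonRoot$bpRaw), 1e-12) / 200)
  expect_true(all(abs(nonRoot$bp - nonRoot$bpRaw) <= 2 * se + 1/200))
})

test_that("well-separated blocks earn AU support above 0.95", {
  for (seed in 1:2) {
    f <- plantedBlockFeatures(10, 50, seed = seed)
    cl <- multiscaleBootstrap(f, nboot = 100, seed = 100 + seed)
    t <- supportTable(cl)
    blocks <- c(paste(sprintf("it%02d", 1:5), collapse = ","),
                paste(sprintf("it%02d", 6:10), collapse = ","))
    for (b in blocks) {
      row <- t[t$members == b, ]
      expect_equal(nrow(row), 1)
      expect_gt(row$au, 0.95)
    }
  }
})
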