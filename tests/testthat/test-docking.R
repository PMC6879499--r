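writeScoresCsv <- function(m, path) deepscreen::writeDockingMatrix(m, path)

test_that("docking CSV reader validates the 0-10 scale and missing cells", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(",p1,p2", "c1,5.0,5.0", "c2,5.0,5.0"), f)
  m <- readDockingMatrix(f)
  expect_s4_class(m, "DockingScoreMatrix")
  expect_true(all(m@.Data == 5))
  writeLines(c(",p1,p2", "c1,5.0,12.3", "c2,5.0,5.0"), f)
  expect_error(readDockingMatrix(f), "c1.*p2|p2.*c1")
  writeLines(c(",p1,p2", "c1,5.0,", "c2,NA,5.0"), f)
  m2 <- readDockingMatrix(f)
  expect_identical(is.na(m2@.Data), matrix(c(FALSE, TRUE, TRUE, FALSE),
                                           2, byrow = TRUE,
                                           dimnames = dimnames(m2@.Data)))
})

test_that("duplicate ids are rejected and orientation can be forced or detected", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(",p1,p1", "c1,5,5", "c2,5,5"), f)
  expect_error(readDockingMatrix(f), "duplicate")
  writeLines(c(",c1,c2,c3", "p1,1,2,3", "p2,4,5,6"), f)
  m <- readDockingMatrix(f, transpose = TRUE)
  expect_identical(compoundIds(m), c("c1", "c2", "c3"))
  mAuto <- readDockingMatrix(f, compoundRef = c("c1", "c2", "c3"))
  expect_identical(compoundIds(mAuto), c("c1", "c2", "c3"))
})

test_that("rank normalization follows the descending average-tie rule", {
  m <- new("DockingScoreMatrix",
           matrix(c(9.1, 7.3, 7.3, 5.0,
                    5, 5, 5, NA,
                    10, 9, 8, 7), 3, 4, byrow = TRUE,
                  dimnames = list(c("a", "b", "c"), paste0("p", 1:4))))
  r <- rankNormalize(m)
  expect_equal(unname(r@.Data["a", ]), c(1, 2.5, 2.5, 4))
  expect_equal(unname(r@.Data["b", ]), c(2, 2, 2, NA))
  expect_equal(unname(r@.Data["c", ]), c(1, 2, 3, 4))
})

test_that("all-missing and single-score rows fail naming the compound", {
  m <- matrix(c(1, 2, NA, NA), 2, 2, byrow = TRUE,
              dimnames = list(c("good", "bad"), c("p1", "p2")))
  dm <- new("DockingScoreMatrix", m)
  expect_error(rankNormalize(dm), "bad")
  m2 <- matrix(c(1, NA, 3, 4), 2, 2, byrow = TRUE,
               dimnames = list(c("single", "full"), c("p1", "p2")))
  expect_error(rankNormalize(new("DockingScoreMatrix", m2)), "single")
})

test_that("rank sums and monotone invariance hold on random matrices", {
  set.seed(11)
  for (rep in 1:25) {
    m <- randomScoreMatrix(6, 10, naFrac = 0.1)
    ok <- rowSums(!is.na(m)) >= 2
    m[!ok, ] <- runif(sum(!ok) * ncol(m), 0, 10)
    dm <- new("DockingScoreMatrix", m)
    r <- rankNormalize(dm)@.Data
    p <- rowSums(!is.na(r))
    expect_equal(unname(rowSums(r, na.rm = TRUE)), unname(p * (p + 1) / 2))
    ## strictly increasing transforms leave ranks untouched
    for (f in list(function(x) x / 2 + 1, function(x) 10 * plogis(x))) {
      mt <- f(m); dimnames(mt) <- dimnames(m)
      rt <- rankNormalize(new("DockingScoreMatrix", mt))@.Data
      expect_identical(rt, r)
    }
  }
})

test_that("docking matrices round-trip through CSV bit-exactly", {
  set.seed(3)
  m <- randomScoreMatrix(5, 7, naFrac = 0.1)
  f <- withr::local_tempfile(fileext = ".csv")
  writeScoresCsv(new("DockingScoreMatrix", m), f)
  back <- readDockingMatrix(f)
  expect_identical(back@.Data, m)
})
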