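test_that("RPM forces each sample total to one million", {
  v <- matrix(c(1, 1, 2, 250000, 250000, 500000), 3, 2,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  m <- OmicsMatrix(v, "expression")
  out <- SummarizedExperiment::assay(normalizeRPM(m), "values")
  expect_equal(out[, "s1"], c(a = 250000, b = 250000, c = 500000))
  expect_equal(out[, "s2"], v[, "s2"])  # already at 1e6: unchanged

  set.seed(8)
  r <- randomOmics(30, 5, seed = 8)
  rn <- normalizeRPM(r)
  expect_equal(colSums(SummarizedExperiment::assay(rn, "values")),
               setNames(rep(1e6, 5), colnames(r)), tolerance = 1e-9)

  v0 <- matrix(c(0, 0, 1, 2), 2, 2,
               dimnames = list(c("a", "b"), c("dead", "ok")))
  expect_error(normalizeRPM(OmicsMatrix(v0, "expression")), "dead")
})

test_that("median-of-ratios matches the hand-computed definition", {
  # 4x2 oracle worked by hand: geometric means per row, per-sample median
  # of counts/geomean over all-positive rows
  v <- matrix(c(2, 4, 6, 0,
                8, 16, 24, 5), 4, 2,
              dimnames = list(paste0("g", 1:4), c("s1", "s2")))
  # all-positive rows: g1..g3; geomean_i = sqrt(v_i1 * v_i2) = (4, 8, 12)
  # ratios s1: (0.5, 0.5, 0.5) -> sf 0.5; s2: (2, 2, 2) -> sf 2
  res <- normalizeMedianOfRatios(OmicsMatrix(v, "expression"))
  expect_equal(res$sizeFactors, c(s1 = 0.5, s2 = 2))
  out <- SummarizedExperiment::assay(res$matrix, "values")
  expect_equal(unname(out[, "s1"]), c(4, 8, 12, 0))
  expect_equal(unname(out[, "s2"]), c(4, 8, 12, 2.5))

  # identical columns: both factors 1, matrix unchanged
  v2 <- matrix(c(3, 7, 9, 3, 7, 9), 3, 2,
               dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  res2 <- normalizeMedianOfRatios(OmicsMatrix(v2, "expression"))
  expect_equal(res2$sizeFactors, c(s1 = 1, s2 = 1))
  expect_equal(SummarizedExperiment::assay(res2$matrix, "values"), v2)

  # scaling one column by c scales its size factor by c (up to the common
  # geometric-mean rescaling of all factors)
  set.seed(3)
  cnt <- matrix(rpois(40 * 4, 60) + 1, 40, 4,
                dimnames = list(sprintf("g%02d", 1:40), sprintf("s%d", 1:4)))
  sf1 <- normalizeMedianOfRatios(OmicsMatrix(cnt, "expression"))$sizeFactors
  cnt2 <- cnt; cnt2[, 2] <- cnt2[, 2] * 3
  sf2 <- normalizeMedianOfRatios(OmicsMatrix(cnt2, "expression"))$sizeFactors
  ratio <- sf2 / sf1
  expect_equal(ratio[[2]] / ratio[[1]], 3, tolerance = 1e-9)

  expect_error(
    normalizeMedianOfRatios(OmicsMatrix(
      matrix(c(0, 1, 1, 0), 2, 2,
             dimnames = list(c("a", "b"), c("s1", "s2"))), "expression")),
    "size factors undefined")
})

test_that("median-of-ratios agrees with the DESeq2 size-factor estimator", {
  skip_if_not_installed("DESeq2")
  set.seed(11)
  cnt <- matrix(rpois(150 * 6, 80), 150, 6,
                dimnames = list(sprintf("g%03d", 1:150), sprintf("s%d", 1:6)))
  sf <- normalizeMedianOfRatios(OmicsMatrix(cnt, "expression"))$sizeFactors
  ref <- DESeq2::estimateSizeFactorsForMatrix(cnt)
  expect_equal(unname(sf), unname(ref), tolerance = 1e-12)
})

test_that("log2 and pseudo-log transforms behave as declared", {
  v <- matrix(c(0, 1, 3, 10, 100, 1e6), 3, 2,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  m <- OmicsMatrix(v, "expression")
  lg <- SummarizedExperiment::assay(transformValues(m, "log2"), "values")
  expect_equal(lg[, "s1"], c(a = 0, b = 1, c = 2))  # log2(x + 1)
  ps <- SummarizedExperiment::assay(transformValues(m, "pseudoLog"), "values")
  expect_equal(ps[["a", "s1"]], 0)
  # asymptotically log2: ratio within 1% at 1e6
  expect_equal(ps[["c", "s2"]] / log2(1e6), 1, tolerance = 0.01)
  # monotone per entry, shape and ids preserved
  expect_identical(dimnames(ps), dimnames(v))
  expect_true(all(order(v[, 1]) == order(ps[, 1])))
  vneg <- matrix(c(-1, 2, 3, 4), 2, 2,
                 dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(transformValues(OmicsMatrix(vneg, "expression"), "log2"),
               "negative")
})

test_that("CV selection matches a brute-force sd/mean ranking", {
  set.seed(21)
  v <- matrix(rlnorm(100 * 8, 4, 1.2), 100, 8,
              dimnames = list(sprintf("g%03d", 1:100), sprintf("s%d", 1:8)))
  v[7, ] <- 5                     # constant feature: CV 0
  m <- OmicsMatrix(v, "expression")
  sel <- selectFeaturesByCV(m, 30)
  cv <- apply(v, 1, sd) / rowMeans(v)
  oracle <- sort(rownames(v)[order(cv, decreasing = TRUE)[1:30]])
  expect_identical(sort(rownames(sel)), oracle)
  # original row order preserved among the selected
  expect_identical(rownames(sel),
                   rownames(v)[rownames(v) %in% rownames(sel)])
  expect_false("g007" %in% rownames(sel))
  # n_top = all features: identity
  expect_identical(rownames(selectFeaturesByCV(m, 100)), rownames(v))
  expect_error(selectFeaturesByCV(m, 101), "exceeds")
})

test_that("CV ranking is invariant under global positive scaling", {
  m <- randomOmics(50, 6, seed = 31)
  v <- SummarizedExperiment::assay(m, "values")
  m2 <- OmicsMatrix(v * 37.5, "expression")
  expect_identical(rownames(selectFeaturesByCV(m, 10)),
                   rownames(selectFeaturesByCV(m2, 10)))
})
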