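test_that("CSV reader accepts boundary beta-values and preserves layout", {
  v <- matrix(c(0, 0.5, 1, 0.25, 0.75, 0.1), 3, 2,
              dimnames = list(c("cg1", "cg2", "cg3"), c("s1", "s2")))
  path <- withr::local_tempfile(fileext = ".csv")
  writeMatrixFixture(v, path)
  m <- readOmicsCSV(path, "methylation")
  expect_s4_class(m, "OmicsMatrix")
  expect_identical(modality(m), "methylation")
  expect_identical(rownames(m), rownames(v))
  expect_identical(colnames(m), colnames(v))
  expect_equal(SummarizedExperiment::assay(m, "values"), v)
})

test_that("reader errors name duplicated ids, bad cells and range violations", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,s1,s2", "TP53,1,2", "BRCA1,3,4", "TP53,5,6"), path)
  expect_error(readOmicsCSV(path, "expression"), "TP53")

  writeLines(c("id,s1,s2", "g1,1,2", "g2,oops,4"), path)
  expect_error(readOmicsCSV(path, "expression"), "g2.*s1")

  writeLines(c("id,s1,s2", "cg1,0.2,1.4", "cg2,0.1,0.3"), path)
  expect_error(readOmicsCSV(path, "methylation"), "cg1")

  expect_error(readOmicsCSV(tempfile(), "expression"), "not found")
})

test_that("write/read round trip is the identity on simulated data", {
  sim <- simulateExpressionMixture(K = 3, nFeatures = 50, nSamples = 10,
                                   nMarkersPerComponent = 5, noiseSd = 0.1,
                                   seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  writeOmicsCSV(sim$matrix, path)
  back <- readOmicsCSV(path, "expression")
  expect_identical(dimnames(back), dimnames(sim$matrix))
  expect_equal(SummarizedExperiment::assay(back, "values"),
               SummarizedExperiment::assay(sim$matrix, "values"),
               tolerance = 1e-12)
})

test_that("invariants are enforced at construction", {
  v <- matrix(1:4, 2, 2, dimnames = list(c("a", "b"), c("s", "s")))
  expect_error(OmicsMatrix(v, "expression"), "duplicated sample")
  v2 <- matrix(c(0.2, 1.7, 0.3, 0.4), 2, 2,
               dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(OmicsMatrix(v2, "methylation"), "\\[0, 1\\]")
  v3 <- matrix(c(1, NA, 2, 3), 2, 2,
               dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(OmicsMatrix(v3, "expression"), "finite")
  expect_error(OmicsMatrix(unname(v3), "expression"))
})

test_that("subsetting keeps class and modality", {
  m <- randomOmics(10, 4, seed = 2, modality = "methylation")
  sub <- m[3:7, 1:2]
  expect_s4_class(sub, "OmicsMatrix")
  expect_identical(modality(sub), "methylation")
  expect_identical(dim(sub), c(5L, 2L))
})
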