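test_that("noiseless expression mixtures factor exactly and are reproducible", {
  s1 <- simulateExpressionMixture(K = 3, nFeatures = 90, nSamples = 8,
                                  nMarkersPerComponent = 6, noiseSd = 0,
                                  seed = 11)
  X <- SummarizedExperiment::assay(s1$matrix, "values")
  expect_equal(X, profiles(s1$truth) %*% proportions(s1$truth),
               tolerance = 1e-12)
  s2 <- simulateExpressionMixture(K = 3, nFeatures = 90, nSamples = 8,
                                  nMarkersPerComponent = 6, noiseSd = 0,
                                  seed = 11)
  expect_identical(X, SummarizedExperiment::assay(s2$matrix, "values"))
  s3 <- simulateExpressionMixture(K = 3, nFeatures = 90, nSamples = 8,
                                  nMarkersPerComponent = 6, noiseSd = 0,
                                  seed = 12)
  expect_false(identical(X, SummarizedExperiment::assay(s3$matrix, "values")))
})

test_that("simulator truths satisfy the mixture invariants", {
  s <- simulateExpressionMixture(K = 4, nFeatures = 200, nSamples = 12,
                                 nMarkersPerComponent = 10, noiseSd = 0.1,
                                 seed = 13)
  expect_simplex_columns(proportions(s$truth))
  expect_identical(anyDuplicated(unlist(markerSets(s$truth))), 0L)
  expect_identical(modality(s$matrix), "expression")
  expect_s4_class(s$matrix, "OmicsMatrix")   # finite, ids, etc. validated
  mm <- matchComponents(proportions(s$truth), proportions(s$truth))
  expect_equal(mm$mae, 0)
  expect_error(
    simulateExpressionMixture(K = 4, nFeatures = 30, nSamples = 6,
                              nMarkersPerComponent = 10, noiseSd = 0,
                              seed = 1),
    "capacity")
})

test_that("marker structure and purity options shape the profiles", {
  s <- simulateExpressionMixture(K = 2, nFeatures = 60, nSamples = 6,
                                 nMarkersPerComponent = 5, noiseSd = 0,
                                 seed = 17, pureMarkers = TRUE,
                                 pureSamples = 2)
  Tm <- profiles(s$truth)
  for (k in 1:2) {
    idx <- match(markerSets(s$truth)[[k]], rownames(Tm))
    expect_true(all(Tm[idx, -k] == 0))
    expect_true(all(Tm[idx, k] > 0))
  }
  A <- proportions(s$truth)
  expect_equal(unname(A[, 1:4]),
               unname(cbind(c(1, 0), c(0, 1), c(1, 0), c(0, 1))))
})

test_that("methylation mixtures stay in the unit interval with aligned anchors", {
  s <- simulateMethylationMixture(K = 3, nFeatures = 150, nSamples = 10,
                                  nAnchorCpgs = 5, noiseSd = 0.2, seed = 19)
  X <- SummarizedExperiment::assay(s$matrix, "values")
  expect_gte(min(X), 0)
  expect_lte(max(X), 1)
  expect_identical(modality(s$matrix), "methylation")
  # anchors: 0.95 in their component, 0.05 elsewhere
  Tm <- profiles(s$truth)
  g1 <- s$cpgMap$cpg[s$cpgMap$gene %in% markerSets(s$truth)[[1]]]
  anchors1 <- intersect(g1[1:5], rownames(Tm))
  expect_true(all(Tm[anchors1, 1] == 0.95))
  expect_true(all(Tm[anchors1, -1] == 0.05))
  # marker gene sets disjoint and aligned to the CpG->gene triples
  expect_identical(anyDuplicated(unlist(markerSets(s$truth))), 0L)
  expect_identical(nrow(s$cpgMap), 150L)
})
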