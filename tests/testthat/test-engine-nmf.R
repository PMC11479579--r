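test_that("noiseless mixtures with perfect markers are recovered exactly", {
  sim <- simulateExpressionMixture(K = 2, nFeatures = 200, nSamples = 12,
                                   nMarkersPerComponent = 8, noiseSd = 0,
                                   seed = 7, pureMarkers = TRUE,
                                   pureSamples = 1)
  fit <- nmfDeconvolve(sim$matrix, K = 2, seed = 7)
  mm <- matchComponents(fit, proportions(sim$truth))
  expect_lt(max(abs(proportions(fit)[mm$permutation, ] -
                    proportions(sim$truth))), 1e-3)
})

test_that("K = 1 collapses to a unit proportion row", {
  m <- randomOmics(30, 6, seed = 12)
  fit <- nmfDeconvolve(m, K = 1, seed = 12)
  expect_equal(unname(proportions(fit)), matrix(1, 1, 6))
  expect_gte(min(profiles(fit)), 0)
})

test_that("profiles from the pseudoinverse step are clamped at zero", {
  sim <- simulateExpressionMixture(K = 3, nFeatures = 300, nSamples = 15,
                                   nMarkersPerComponent = 10, noiseSd = 0.3,
                                   seed = 19)
  fit <- nmfDeconvolve(sim$matrix, K = 3, seed = 19)
  Tm <- profiles(fit)
  expect_gte(min(Tm), 0)
  # noisy pseudoinverse refits always produce some negatives -> exact zeros
  expect_gt(sum(Tm == 0), 0)
})

test_that("the RSS trace is non-increasing and the fit is deterministic", {
  sim <- simulateExpressionMixture(K = 3, nFeatures = 150, nSamples = 12,
                                   nMarkersPerComponent = 8, noiseSd = 0.1,
                                   seed = 23)
  f1 <- nmfDeconvolve(sim$matrix, K = 3, seed = 5)
  f2 <- nmfDeconvolve(sim$matrix, K = 3, seed = 5)
  expect_identical(proportions(f1), proportions(f2))
  expect_identical(profiles(f1), profiles(f2))
  expect_monotone_trace(rssTrace(f1))
  expect_simplex_columns(proportions(f1))
})

test_that("invalid K and negative input are rejected", {
  m <- randomOmics(10, 5, seed = 1)
  expect_error(nmfDeconvolve(m, K = 5, seed = 1), "smaller")
  v <- matrix(c(-1, 2, 3, 4), 2, 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(nmfDeconvolve(OmicsMatrix(v, "expression"), K = 1, seed = 1),
               "non-negative")
})
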