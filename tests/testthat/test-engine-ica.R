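test_that("component reorientation flips on the dominant absolute weight", {
  r <- reorientComponents(cbind(c(-5, 1, 2), c(5, -1, 2)))
  expect_equal(r$signs, c(-1, 1))
  expect_equal(r$weights[, 1], c(5, -1, -2))
  expect_equal(r$weights[, 2], c(5, -1, 2))
  expect_error(reorientComponents(cbind(c(1, 2), c(0, 0))), "all-zero")
})

test_that("reorientation is idempotent on random matrices", {
  set.seed(41)
  for (i in 1:10) {
    W <- matrix(rnorm(40), 10, 4)
    once <- reorientComponents(W)$weights
    twice <- reorientComponents(once)
    expect_identical(twice$weights, once)
    expect_equal(twice$signs, rep(1, 4))
  }
})

test_that("marker scoring defaults to 30 and reduces to the mean for equal weights", {
  expect_identical(eval(formals(icaDeconvolve)$nMarkers), 30L)
  set.seed(43)
  X <- matrix(rlnorm(50 * 6), 50, 6)
  w <- rep(0.7, 50)
  expect_equal(demix:::.componentScores(X, w, 1:10),
               colMeans(X[1:10, ]))
})

test_that("independent heavy-tailed sources are separated", {
  set.seed(47)
  nF <- 1000
  T0 <- matrix(rlnorm(nF * 2, 3, 2), nF, 2)   # heavy-tailed, independent
  A0 <- matrix(runif(2 * 20, 0.1, 1), 2, 20)
  X <- T0 %*% A0
  dimnames(X) <- list(sprintf("g%04d", 1:nF), sprintf("s%02d", 1:20))
  fit <- icaDeconvolve(OmicsMatrix(X, "expression"), K = 2, seed = 47)
  truthProp <- sweep(A0, 2, colSums(A0), "/")
  mm <- matchComponents(fit, truthProp)
  expect_gt(min(mm$correlations), 0.9)
  expect_simplex_columns(proportions(fit))
  expect_gte(min(profiles(fit)), 0)
  # determinism
  fit2 <- icaDeconvolve(OmicsMatrix(X, "expression"), K = 2, seed = 47)
  expect_identical(proportions(fit), proportions(fit2))
})

test_that("raw abundance scores are returned when rescaling is disabled", {
  set.seed(53)
  X <- matrix(rlnorm(400 * 2, 3, 2), 400, 2) %*%
    matrix(runif(2 * 12, 0.2, 1), 2, 12)
  dimnames(X) <- list(sprintf("g%03d", 1:400), sprintf("s%02d", 1:12))
  raw <- icaDeconvolve(OmicsMatrix(X, "expression"), K = 2, seed = 53,
                       rescale = FALSE)
  expect_type(raw, "list")
  expect_named(raw, c("scores", "weights"))
  expect_false(isTRUE(all.equal(unname(colSums(raw$scores)), rep(1, 12))))
})
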