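# Shared fixture builders and independent oracles for the test suite.
# All fixtures are generated in code under fixed seeds; nothing is stored.

# Small OmicsMatrix with reproducible random content.
randomOmics <- function(nF = 20, nS = 6, seed = 1, modality = "expression") {
  set.seed(seed)
  v <- if (modality == "methylation")
    matrix(runif(nF * nS), nF, nS)
  else
    matrix(rlnorm(nF * nS, 3, 1), nF, nS)
  dimnames(v) <- list(sprintf("g%03d", seq_len(nF)),
                      sprintf("s%02d", seq_len(nS)))
  OmicsMatrix(v, modality)
}

# Write a features x samples matrix to a CSV in the expected exchange layout.
writeMatrixFixture <- function(v, path) {
  df <- data.frame(feature_id = rownames(v), v, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  path
}

# Independent oracle: enrichment-score by the naive O(N) running sum.
naiveRunningSumES <- function(scores, memberIdx, p = 1) {
  N <- length(scores)
  inset <- seq_len(N) %in% memberIdx
  inc <- ifelse(inset,
                abs(scores)^p / sum(abs(scores[inset])^p),
                -1 / (N - sum(inset)))
  run <- cumsum(inc)
  run[which.max(abs(run))]
}

# Independent oracle: hypergeometric tail by exhaustive enumeration of all
# possible selections of size selSize from a small universe.
enumerationTailP <- function(universeSize, setSize, selSize, observedOverlap) {
  sel <- combn(universeSize, selSize)
  inSet <- seq_len(setSize)   # wlog the set is the first setSize elements
  hits <- apply(sel, 2L, function(s) sum(s %in% inSet))
  mean(hits >= observedOverlap)
}

# Ground-truth mixture with balanced per-component total abundance (equal
# row sums of A), needed for exact corner recovery in the CAM geometry.
balancedProportions <- function(K, nBlocks, seed) {
  set.seed(seed)
  base <- matrix(rgamma(K * nBlocks, 1), K)
  base <- sweep(base, 2, colSums(base), "/")
  do.call(cbind, lapply(0:(K - 1), function(s)
    base[((0:(K - 1) + s) %% K) + 1L, , drop = FALSE]))
}

expect_simplex_columns <- function(A, tol = 1e-6) {
  expect_gte(min(A), -1e-9)
  expect_lt(max(abs(colSums(A) - 1)), tol)
}

expect_monotone_trace <- function(tr) {
  if (length(tr) > 1)
    expect_lte(max(diff(tr)), 1e-9 * max(1, tr[1]))
}
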