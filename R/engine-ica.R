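#' Reorient component weight vectors
#'
#' Flips the sign of each component column so that its largest-magnitude
#' entry is positive (ties broken by the smallest row index), under the
#' convention that a component's strongest weights should be positive
#' contributions. Idempotent.
#'
#' @param weights Numeric features x K matrix with no all-zero column.
#' @return A list with `weights` (the reoriented matrix) and `signs` (the
#'   per-component factor, +1 or -1, that was applied).
#' @examples
#' reorientComponents(cbind(c(-5, 1, 2)))$signs
#' @export
reorientComponents <- function(weights) {
  weights <- as.matrix(weights)
  if (any(colSums(abs(weights)) == 0))
    stop("all-zero component column(s): ",
         paste(which(colSums(abs(weights)) == 0), collapse = ", "),
         call. = FALSE)
  signs <- vapply(seq_len(ncol(weights)), function(k) {
    col <- weights[, k]
    top <- which.max(abs(col))  # ties: first (smallest) row index
    if (col[top] < 0) -1 else 1
  }, numeric(1))
  list(weights = sweep(weights, 2L, signs, "*"), signs = signs)
}

# Minimal FastICA (parallel/symmetric variant, logcosh nonlinearity).
# X: observations x variables, column-centered and whitened internally via
# its top-nComp principal subspace. Returns the source matrix S
# (observations x nComp, unit variance columns). Consumes the RNG stream for
# the random orthonormal start.
.fastICA <- function(X, nComp, maxit = 500L, tol = 1e-7, alpha = 1) {
  n <- nrow(X)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  cv <- crossprod(Xc) / (n - 1)
  eg <- eigen(cv, symmetric = TRUE)
  if (sum(eg$values > 1e-12 * eg$values[1L]) < nComp)
    stop("matrix rank is below the requested number of components",
         call. = FALSE)
  Kw <- eg$vectors[, seq_len(nComp), drop = FALSE] %*%
    diag(1 / sqrt(eg$values[seq_len(nComp)]), nComp)
  Z <- Xc %*% Kw                      # whitened: crossprod(Z)/(n-1) = I
  W <- matrix(rnorm(nComp * nComp), nComp)
  W <- .symOrth(W)
  for (it in seq_len(maxit)) {
    U <- Z %*% t(W)                   # current source estimates
    gU <- tanh(alpha * U)
    gPrime <- alpha * (1 - gU^2)
    W1 <- crossprod(gU, Z) / n - diag(colMeans(gPrime), nComp) %*% W
    W1 <- .symOrth(W1)
    conv <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (conv < tol) break
  }
  Z %*% t(W)
}

.symOrth <- function(W) {
  sv <- svd(W)
  sv$u %*% t(sv$v)
}

# Weighted-mean component score of each sample over the marker rows.
.componentScores <- function(X, weights, markerIdx) {
  w <- weights[markerIdx]
  drop(crossprod(w, X[markerIdx, , drop = FALSE])) / sum(w)
}

#' Deconvolution by independent component analysis with marker scoring
#'
#' Runs a FastICA-style blind source separation on the (row-centered)
#' features x samples matrix to extract K statistically independent
#' components over features. Each component is reoriented
#' ([reorientComponents()]), its `nMarkers` top-weighted features are taken
#' as markers, and each sample receives the weighted mean of its marker rows
#' (weights = component weights) as the component abundance score. Scores
#' are assembled into a K x samples matrix and, by default, each sample
#' column is projected onto the simplex by dividing by its column sum to
#' yield proportions; ICA itself produces abundance scores, not proportions,
#' so this rescaling can be disabled with `rescale = FALSE` (the result then
#' no longer satisfies the simplex contract and is returned as a plain
#' list).
#'
#' @param m An [OmicsMatrix] with at least K samples.
#' @param K Number of components.
#' @param seed Integer seed (random orthonormal start of the fixed-point
#'   iteration).
#' @param nMarkers Markers per component used for scoring (default 30).
#' @param rescale Project per-sample scores onto the simplex (default TRUE).
#' @return A [DeconvolutionResult] with `engine = "ica"` (or, when
#'   `rescale = FALSE`, a list with elements `scores` and `weights`).
#' @export
icaDeconvolve <- function(m, K, seed, nMarkers = 30L, rescale = TRUE) {
  stopifnot(is(m, "OmicsMatrix"))
  X <- .values(m)
  K <- .checkCount(K, "K")
  if (ncol(X) < K)
    stop("ICA needs at least K samples", call. = FALSE)
  nMarkers <- .checkCount(nMarkers, "nMarkers")
  nMarkers <- min(nMarkers, nrow(X))
  seed <- .checkSeed(seed)
  Xrc <- X - rowMeans(X)              # row-centered internally
  S <- .withSeed(seed, .fastICA(Xrc, K))
  S <- reorientComponents(S)$weights
  scores <- matrix(0, K, ncol(X))
  for (k in seq_len(K)) {
    ord <- order(S[, k], decreasing = TRUE)
    markers <- ord[seq_len(nMarkers)]
    scores[k, ] <- .componentScores(X, S[, k], markers)
  }
  if (!rescale) {
    dimnames(scores) <- list(.componentNames(K), colnames(X))
    Tm <- pmax(S, 0)
    dimnames(Tm) <- list(rownames(X), .componentNames(K))
    return(list(scores = scores, weights = Tm))
  }
  cs <- colSums(scores)
  if (any(cs <= 0))
    stop("non-positive component score sum for sample(s): ",
         paste(colnames(X)[cs <= 0], collapse = ", "), call. = FALSE)
  A <- sweep(scores, 2L, cs, "/")
  Tm <- pmax(S, 0)                    # component weights, negatives clamped
  if (modality(m) == "methylation") Tm <- pmin(Tm, 1)
  .newResult(A, Tm, engine = "ica", modality = modality(m),
             rssTrace = numeric(0), nIterations = 1L, seed = seed,
             featureIds = rownames(X), sampleIds = colnames(X),
             diagnostics = list(nMarkers = nMarkers))
}
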