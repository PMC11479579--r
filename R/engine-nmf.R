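#' Deconvolution by simplex-constrained non-negative matrix factorization
#'
#' Factorizes a non-negative matrix X (features x samples) as T A with
#' T >= 0 and every column of A on the probability simplex, by alternating
#' exact constrained least squares:
#' \enumerate{
#'   \item T-step: per feature, non-negative least squares of X on A.
#'   \item A-step: per sample, least squares on T under the simplex
#'     constraint (entries >= 0, summing to 1), so proportions are valid by
#'     construction.
#' }
#' Because each step is an exact constrained minimizer, the residual sum of
#' squares is non-increasing. After convergence, T is recomputed as
#' `X %*% ginv(A)` (Moore-Penrose pseudoinverse) and any negative entries of
#' the recomputed T are set to 0 — the standard post-processing that sharpens
#' profiles once proportions are fixed.
#'
#' The first start is initialized from a convex-geometry corner guess
#' (k-means on row-normalized features, farthest-point corner sweep); the
#' remaining `nStarts - 1` starts are random simplex draws and replace it
#' only if they improve the RSS by more than a 0.1\% relative margin (smaller differences are convergence-depth noise within the flat region). The
#' geometric start resolves the near-flat scaling indeterminacy of the
#' factorization toward the vertex-consistent solution.
#'
#' @param m A non-negative [OmicsMatrix].
#' @param K Number of components, `K < min(dim(m))`.
#' @param seed Integer seed for the random initializations.
#' @param maxIter Maximum alternating iterations per start (default 500).
#' @param tol Relative RSS-change stopping tolerance (default 1e-6).
#' @param nStarts Number of seeded random restarts; the best final RSS is
#'   kept (default 3).
#' @return A [DeconvolutionResult] with `engine = "nmf"`.
#' @examples
#' sim <- simulateExpressionMixture(K = 2, nFeatures = 120, nSamples = 12,
#'                                  nMarkersPerComponent = 10, noiseSd = 0,
#'                                  seed = 7)
#' fit <- nmfDeconvolve(sim$matrix, K = 2, seed = 7)
#' matchComponents(fit, proportions(sim$truth))$mae
#' @export
nmfDeconvolve <- function(m, K, seed, maxIter = 500L, tol = 1e-6,
                          nStarts = 3L) {
  stopifnot(is(m, "OmicsMatrix"))
  X <- .values(m)
  K <- .checkCount(K, "K")
  if (K >= min(dim(X)))
    stop(sprintf("K (%d) must be smaller than both dimensions (%d x %d)",
                 K, nrow(X), ncol(X)), call. = FALSE)
  if (min(X) < 0) stop("NMF requires non-negative values", call. = FALSE)
  seed <- .checkSeed(seed)
  best <- .withSeed(seed,
    .alsMultiStart(X, K, nStarts, maxIter = maxIter, tol = tol,
                   tolType = "relative", profileUpper = Inf))
  A <- best$A
  rankA <- qr(A)$rank
  diagnostics <- list(nStarts = nStarts, converged = best$converged)
  if (rankA < K) {
    warning("estimated proportion matrix is rank-deficient (rank ",
            rankA, " < K = ", K, ")")
    diagnostics$rankDeficient <- TRUE
  }
  Tm <- X %*% MASS::ginv(A)   # pseudoinverse refit of the profiles
  Tm[Tm < 0] <- 0             # clamp: profiles cannot be negative
  if (modality(m) == "methylation") Tm[Tm > 1] <- 1
  .newResult(A, Tm, engine = "nmf", modality = modality(m),
             rssTrace = best$trace, nIterations = length(best$trace),
             seed = seed, featureIds = rownames(X), sampleIds = colnames(X),
             diagnostics = diagnostics)
}

# Convex-geometry initialization of A: row-normalized features populate the
# simplex spanned by the (scaled) proportion rows, so k-means centers of the
# scaled rows hug that simplex and a farthest-point sweep over the centers
# picks near-corner representatives. Deterministic given the RNG stream.
# Returns NULL when the matrix is too small for the clustering.
.geomInitA <- function(X, K, clusterFactor = 5L) {
  rs <- rowSums(X)
  usable <- rs > 0
  if (K < 2L || sum(usable) <= 2L * K) return(NULL)
  R <- X[usable, , drop = FALSE] / rs[usable]
  nc <- min(clusterFactor * K, nrow(R) - 1L)
  km <- tryCatch(
    suppressWarnings(stats::kmeans(R, centers = nc, nstart = 5L,
                                   iter.max = 100L)),
    error = function(e) NULL)
  if (is.null(km)) return(NULL)
  C <- km$centers
  spread <- rowSums(sweep(C, 2L, colMeans(C))^2)
  chosen <- which.max(spread)
  while (length(chosen) < K) {
    d <- apply(C, 1L, function(r)
      min(colSums((t(C[chosen, , drop = FALSE]) - r)^2)))
    chosen <- c(chosen, which.max(d))
  }
  A <- C[chosen, , drop = FALSE]
  cs <- colSums(A)
  if (any(cs <= 0)) return(NULL)
  sweep(A, 2L, cs, "/")
}

# Multi-start driver: the first start is the deterministic convex-geometry
# corner initialization, the rest are random simplex draws. Because the
# zero-residual set of the factorization is typically a flat region (any
# slight expansion of the mixing simplex refits exactly), final RSS values of
# different starts tie at noise level; within such ties the geometric start
# is the vertex-consistent representative and is preferred. A random start
# replaces it only when its RSS is better by more than a 1e-3 relative
# margin.
.alsMultiStart <- function(X, K, nStarts, ...) {
  starts <- vector("list", nStarts)
  g <- .geomInitA(X, K)
  for (s in seq_len(nStarts)) {
    initA <- if (s == 1L && !is.null(g)) g else NULL
    starts[[s]] <- .alsFactorize(X, K, ..., initA = initA)
  }
  best <- starts[[1L]]
  for (s in seq_len(nStarts)[-1L])
    if (starts[[s]]$rss < best$rss * (1 - 1e-3)) best <- starts[[s]]
  best
}

# Shared alternating constrained least-squares core (NMF and EDec engines).
# profileUpper = Inf: T >= 0 (expression); profileUpper = 1: T in [0, 1]
# (beta-values). Stopping: relative RSS change < tol (tolType "relative") or
# absolute RSS change < tol (tolType "absolute"). Consumes the current RNG
# stream for its random simplex initialization of A unless initA is given.
.alsFactorize <- function(X, K, maxIter, tol, tolType, profileUpper,
                          initA = NULL) {
  A <- if (is.null(initA)) .runifSimplex(K, ncol(X)) else initA
  trace <- numeric(0)
  rss <- Inf
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    GA <- .gram(t(A))
    Tm <- if (is.finite(profileUpper))
      t(.lsBox(t(A), t(X), lo = 0, hi = profileUpper, G = GA))
    else
      t(.lsNonneg(t(A), t(X), G = GA))
    A <- .lsSimplex(Tm, X)
    newRss <- .frobRSS(X, Tm, A)
    trace <- c(trace, newRss)
    delta <- rss - newRss
    stopNow <- if (tolType == "relative") {
      is.finite(rss) && abs(delta) / max(rss, .Machine$double.eps) < tol
    } else {
      is.finite(rss) && abs(delta) < tol
    }
    rss <- newRss
    if (stopNow) { converged <- TRUE; break }
  }
  list(A = A, T = Tm, rss = rss, trace = trace, converged = converged)
}

#' EDec-style deconvolution of methylation beta-values
#'
#' Iterative constrained matrix factorization for DNA-methylation mixtures:
#' minimizes the Euclidean distance between the reconstituted and observed
#' beta-value matrices under the constraints that cell-type methylation
#' profiles lie in \[0, 1\] and per-sample proportions lie on the simplex.
#' Each iteration alternates (a) per-CpG box-constrained least squares for
#' the profile matrix T given A and (b) per-sample simplex-constrained least
#' squares for A given T; both are exact minimizers, so the RSS trace is
#' non-increasing. Iteration stops when the absolute RSS change drops below
#' `rssDiffStop` or after `maxIts` iterations. As for [nmfDeconvolve()], the
#' first of the `nRestarts` seeded starts uses the convex-geometry corner
#' initialization; random restarts supersede it only on a clear RSS
#' improvement.
#'
#' @param m A methylation [OmicsMatrix] (beta-values in \[0, 1\]).
#' @param K Number of components, `K < ncol(m)`.
#' @param seed Integer seed.
#' @param maxIts Maximum iterations per restart (default 2000).
#' @param rssDiffStop Absolute RSS-change stopping threshold (default 1e-10).
#' @param nRestarts Number of random restarts (default 5).
#' @return A [DeconvolutionResult] with `engine = "edec"`.
#' @export
edecDeconvolve <- function(m, K, seed, maxIts = 2000L, rssDiffStop = 1e-10,
                           nRestarts = 5L) {
  stopifnot(is(m, "OmicsMatrix"))
  if (modality(m) != "methylation")
    stop("edecDeconvolve requires a methylation (beta-value) matrix",
         call. = FALSE)
  X <- .values(m)
  K <- .checkCount(K, "K")
  if (K >= ncol(X))
    stop(sprintf("K (%d) must be smaller than the number of samples (%d)",
                 K, ncol(X)), call. = FALSE)
  seed <- .checkSeed(seed)
  best <- .withSeed(seed,
    .alsMultiStart(X, K, nRestarts, maxIter = maxIts, tol = rssDiffStop,
                   tolType = "absolute", profileUpper = 1))
  Tm <- best$T
  Tm[Tm < 0] <- 0
  Tm[Tm > 1] <- 1
  .newResult(best$A, Tm, engine = "edec", modality = "methylation",
             rssTrace = best$trace, nIterations = length(best$trace),
             seed = seed, featureIds = rownames(X), sampleIds = colnames(X),
             diagnostics = list(nRestarts = nRestarts,
                                converged = best$converged))
}

#' Run a deconvolution engine by name
#'
#' Convenience dispatcher over [nmfDeconvolve()], [icaDeconvolve()],
#' [edecDeconvolve()] and [camLiteDeconvolve()].
#'
#' @param m An [OmicsMatrix].
#' @param K Number of components.
#' @param engine One of `"nmf"`, `"ica"`, `"edec"`, `"cam_lite"`.
#' @param seed Integer seed.
#' @param ... Extra arguments passed to the engine.
#' @return A [DeconvolutionResult].
#' @export
deconvolve <- function(m, K, engine = c("nmf", "ica", "edec", "cam_lite"),
                       seed, ...) {
  engine <- match.arg(engine)
  switch(engine,
    nmf = nmfDeconvolve(m, K, seed, ...),
    ica = icaDeconvolve(m, K, seed, ...),
    edec = edecDeconvolve(m, K, seed, ...),
    cam_lite = camLiteDeconvolve(m, K, seed, ...))
}
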