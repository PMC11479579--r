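#' Simplified convex-geometry (CAM-style) deconvolution
#'
#' A geometric vertex search in the sample-composition simplex, inspired by
#' convex analysis of mixtures: each feature row of a non-negative mixture
#' X = T A, scaled to sum 1, is a convex combination of the rows of A scaled
#' likewise, so the scaled rows populate a simplex whose corners are the
#' (scaled) proportion rows. The engine
#' \enumerate{
#'   \item scales each feature row to sum 1,
#'   \item clusters the scaled rows with k-means into `clusterFactor * K`
#'     clusters (seeded),
#'   \item scores every K-subset of cluster centers by the total squared
#'     residual of the remaining centers under their best convex combination
#'     of the subset, and keeps the subset with minimal score (margin-based
#'     corner identification),
#'   \item renormalizes the chosen corner rows per sample column to obtain A,
#'   \item recovers T by per-feature non-negative least squares of X on A.
#' }
#' The K-subset search is exhaustive, so K is limited to 6 and
#' `clusterFactor * K` to 60.
#'
#' Note the inherent scale indeterminacy of the geometric view: corners
#' recover the proportion rows only up to a per-component scale, which step 4
#' resolves by projecting columns onto the simplex (exact when the true
#' per-component total abundances are balanced across the cohort).
#'
#' @param m A non-negative [OmicsMatrix].
#' @param K Number of components (<= 6).
#' @param seed Integer seed for k-means.
#' @param clusterFactor Clusters per component (default 5, i.e. `5 * K`
#'   clusters).
#' @return A [DeconvolutionResult] with `engine = "cam_lite"`.
#' @export
camLiteDeconvolve <- function(m, K, seed, clusterFactor = 5L) {
  stopifnot(is(m, "OmicsMatrix"))
  X <- .values(m)
  K <- .checkCount(K, "K")
  clusterFactor <- .checkCount(clusterFactor, "clusterFactor")
  if (K > 6L) stop("camLiteDeconvolve supports K <= 6", call. = FALSE)
  nc <- clusterFactor * K
  if (nc > 60L)
    stop("clusterFactor * K must be <= 60", call. = FALSE)
  if (min(X) < 0) stop("CAM requires non-negative values", call. = FALSE)
  rs <- rowSums(X)
  keep <- rs > 0
  if (nc > sum(keep))
    stop(sprintf("clusterFactor * K (%d) exceeds the number of usable features (%d)",
                 nc, sum(keep)), call. = FALSE)
  if (!all(keep))
    message(sum(!keep), " all-zero feature row(s) ignored by the vertex search")
  R <- X[keep, , drop = FALSE] / rs[keep]   # rows on the simplex
  seed <- .checkSeed(seed)
  km <- .withSeed(seed,
    stats::kmeans(R, centers = nc, nstart = 10L, iter.max = 100L))
  centers <- km$centers                      # nc x samples, rows ~ sum 1
  subsets <- utils::combn(nc, K)
  scoreOf <- function(idx) {
    others <- setdiff(seq_len(nc), idx)
    if (!length(others)) return(0)
    Csub <- t(centers[idx, , drop = FALSE])  # samples x K design
    Fit <- .lsSimplex(Csub, t(centers[others, , drop = FALSE]))
    sum((t(centers[others, , drop = FALSE]) - Csub %*% Fit)^2)
  }
  scores <- apply(subsets, 2L, scoreOf)
  chosen <- subsets[, which.min(scores)]     # ties: first subset, fixed order
  Araw <- centers[chosen, , drop = FALSE]
  cs <- colSums(Araw)
  if (any(cs <= 0))
    stop("degenerate corner set: non-positive column sum", call. = FALSE)
  A <- sweep(Araw, 2L, cs, "/")
  Tm <- t(.lsNonneg(t(A), t(X)))
  if (modality(m) == "methylation") Tm[Tm > 1] <- 1
  rssFinal <- .frobRSS(X, Tm, A)
  .newResult(A, Tm, engine = "cam_lite", modality = modality(m),
             rssTrace = rssFinal, nIterations = 1L, seed = seed,
             featureIds = rownames(X), sampleIds = colnames(X),
             diagnostics = list(clusterFactor = clusterFactor,
                                subsetScore = min(scores),
                                clusterSizes = km$size))
}
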