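#' PCA-eigenvalue scree with an automatic elbow suggestion
#'
#' Computes the PCA eigenvalue spectrum of an omics matrix (features as
#' variables, samples as observations) as guidance for choosing the number
#' of deconvolution components K, plus an advisory elbow (Cattell-style)
#' suggestion of K.
#'
#' The displayed spectrum is the ordinary PCA one (centered by default,
#' optionally scaled). The automatic suggestion, however, is computed on the
#' composition scale: each sample column is divided by its sum, the centered
#' spectrum of the normalized matrix is taken, and the drop-ratio elbow
#' `argmax_k (lambda_k - lambda_{k+1}) / (lambda_{k+1} - lambda_min + 1e-12)`
#' (searched over `k in 1..min(maxK, S-1)`) locates the signal/noise edge.
#' For a K-component mixture with proportions on the simplex, `1'A = 1'`
#' implies the centered composition matrix carries exactly K - 1 signal
#' dimensions, so the suggestion is the elbow plus one. Data whose
#' composition is constant across samples (e.g. a rank-one matrix of one
#' profile under varying depth) suggest K = 1. When the matrix contains
#' negative values the composition scale is undefined and the suggestion
#' falls back to the plain elbow of the displayed spectrum.
#'
#' @param m An [OmicsMatrix] with at least 2 features and 2 samples.
#' @param center,scale Center/scale features for the displayed PCA spectrum
#'   (defaults `TRUE`/`FALSE`: covariance PCA, the usual scree).
#' @param maxK Upper bound of the elbow search (default 10).
#' @return A [ScreeResult].
#' @examples
#' sim <- simulateExpressionMixture(K = 3, nFeatures = 200, nSamples = 20,
#'                                  nMarkersPerComponent = 10,
#'                                  noiseSd = 0.05, seed = 1)
#' nComponents(scree(sim$matrix))
#' @export
scree <- function(m, center = TRUE, scale = FALSE, maxK = 10L) {
  stopifnot(is(m, "OmicsMatrix"))
  v <- .values(m)
  if (nrow(v) < 2L || ncol(v) < 2L)
    stop("scree needs at least 2 features and 2 samples", call. = FALSE)
  if (all(v == v[1L]))
    stop("matrix is constant: no variance to analyze", call. = FALSE)
  if (scale) {
    sdv <- apply(v, 1L, stats::sd)
    if (any(sdv == 0))
      stop("cannot scale: constant feature(s) present, e.g. ",
           rownames(v)[which(sdv == 0)[1L]], call. = FALSE)
  }
  pc <- stats::prcomp(t(v), center = center, scale. = scale)
  ev <- pc$sdev^2
  ev[ev < 0] <- 0
  vf <- ev / sum(ev)
  suggested <- .suggestK(v, maxK, fallbackEv = ev)
  new("ScreeResult", eigenvalues = ev, varianceExplained = vf,
      suggestedK = as.integer(min(suggested, length(ev))),
      centered = isTRUE(center), scaled = isTRUE(scale))
}

# Drop-ratio elbow of a non-increasing eigenvalue vector.
.dropRatioElbow <- function(ev, maxK, S) {
  kMax <- max(1L, min(as.integer(maxK), S - 1L, length(ev) - 1L))
  idx <- seq_len(kMax)
  ratio <- (ev[idx] - ev[idx + 1L]) / (ev[idx + 1L] - min(ev) + 1e-12)
  which.max(ratio)
}

# Mixture-aware K suggestion (see ?scree, Details).
.suggestK <- function(v, maxK, fallbackEv) {
  S <- ncol(v)
  if (min(v) < 0)
    return(.dropRatioElbow(fallbackEv, maxK, S))
  cs <- colSums(v)
  if (any(cs == 0))
    stop("all-zero sample column(s): ",
         paste(colnames(v)[cs == 0], collapse = ", "), call. = FALSE)
  vn <- sweep(v, 2L, cs, "/")                     # composition scale
  pc <- stats::prcomp(t(vn), center = TRUE)
  ev <- pc$sdev^2
  ev[ev < 0] <- 0
  if (sum(ev) <= 1e-18 * sum(vn^2)) return(1L)    # constant composition
  .dropRatioElbow(ev, maxK, S) + 1L
}

#' @describeIn scree Eigenvalue accessor.
#' @param x A `ScreeResult`.
#' @export
setMethod("eigenvalues", "ScreeResult", function(x) x@eigenvalues)

#' @describeIn scree Elbow suggestion accessor (advisory; the eigenvalue
#'   plot is the primary output).
#' @export
setMethod("nComponents", "ScreeResult", function(x) x@suggestedK)

#' Fraction of variance explained per principal component
#'
#' @param x A [ScreeResult].
#' @return Numeric vector summing to 1.
#' @export
varianceExplained <- function(x) {
  stopifnot(is(x, "ScreeResult"))
  x@varianceExplained
}

setMethod("show", "ScreeResult", function(object) {
  cat(sprintf("ScreeResult: %d eigenvalues (center=%s, scale=%s)\n",
              length(object@eigenvalues), object@centered, object@scaled))
  cat("  suggested K (elbow, advisory):", object@suggestedK, "\n")
  cat("  top eigenvalues:",
      paste(signif(utils::head(object@eigenvalues, 8L), 4L), collapse = ", "),
      "\n")
})

#' Scree plot of PCA eigenvalues
#'
#' @param x A [ScreeResult].
#' @param maxK Number of leading eigenvalues to display.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plotScree <- function(x, maxK = 20L, ...) {
  stopifnot(is(x, "ScreeResult"))
  ev <- utils::head(x@eigenvalues, maxK)
  graphics::plot(seq_along(ev), ev, type = "b", pch = 19,
                 xlab = "component", ylab = "eigenvalue",
                 main = "PCA scree", ...)
  graphics::abline(v = x@suggestedK, lty = 2, col = "grey40")
  invisible(x)
}
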