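#' Reads-per-million normalization
#'
#' Scales every sample column of an expression matrix so that its total is
#' 1e6, the classic library-size correction for RNA-seq counts.
#'
#' @param m An expression [OmicsMatrix] with non-negative values.
#' @return An [OmicsMatrix] whose column sums are all 1e6.
#' @export
normalizeRPM <- function(m) {
  stopifnot(is(m, "OmicsMatrix"))
  if (modality(m) != "expression")
    stop("RPM normalization applies to expression matrices only", call. = FALSE)
  v <- .values(m)
  if (min(v) < 0) stop("RPM requires non-negative values", call. = FALSE)
  cs <- colSums(v)
  if (any(cs == 0))
    stop("all-zero sample column(s): ",
         paste(colnames(v)[cs == 0], collapse = ", "), call. = FALSE)
  OmicsMatrix(sweep(v, 2L, cs / 1e6, "/"), modality = "expression")
}

#' Median-of-ratios normalization
#'
#' Library-size correction via size factors: the reference profile is the
#' per-feature geometric mean across samples; each sample's size factor is
#' the median of its ratios to the reference, over the features whose counts
#' are strictly positive in every sample. Each column is then divided by its
#' size factor.
#'
#' @param m An expression [OmicsMatrix] of non-negative counts.
#' @return A list with `matrix` (the normalized [OmicsMatrix]) and
#'   `sizeFactors` (named numeric vector).
#' @export
normalizeMedianOfRatios <- function(m) {
  stopifnot(is(m, "OmicsMatrix"))
  if (modality(m) != "expression")
    stop("median-of-ratios applies to expression matrices only", call. = FALSE)
  v <- .values(m)
  if (min(v) < 0) stop("counts must be non-negative", call. = FALSE)
  allPos <- rowSums(v > 0) == ncol(v)
  if (!any(allPos))
    stop("no feature has positive counts in all samples; size factors undefined",
         call. = FALSE)
  logGeo <- rowMeans(log(v[allPos, , drop = FALSE]))
  logRatios <- log(v[allPos, , drop = FALSE]) - logGeo
  sf <- exp(apply(logRatios, 2L, stats::median))
  names(sf) <- colnames(v)
  list(matrix = OmicsMatrix(sweep(v, 2L, sf, "/"), modality = "expression"),
       sizeFactors = sf)
}

#' Log-type transforms for expression values
#'
#' `"log2"` applies x -> log2(x + 1) (pseudocount so zero counts map to 0).
#' `"pseudoLog"` applies x -> asinh(x / (2 * sigma)) / log(2), the signed
#' pseudo-logarithm: it is 0 at 0, smooth through the origin and
#' asymptotically equal to log2(x / sigma) for large x.
#'
#' @param m An expression [OmicsMatrix] with non-negative values.
#' @param kind `"log2"` or `"pseudoLog"`.
#' @param sigma Linearization scale of the pseudo-log (default 1).
#' @return Transformed [OmicsMatrix], same shape and identifiers.
#' @export
transformValues <- function(m, kind = c("log2", "pseudoLog"), sigma = 1) {
  stopifnot(is(m, "OmicsMatrix"))
  kind <- match.arg(kind)
  if (modality(m) != "expression")
    stop("transforms apply to expression matrices only", call. = FALSE)
  v <- .values(m)
  if (min(v) < 0) stop("negative values cannot be transformed", call. = FALSE)
  out <- switch(kind,
    log2 = log2(v + 1),
    pseudoLog = asinh(v / (2 * sigma)) / log(2))
  OmicsMatrix(out, modality = "expression")
}

#' Select the most variable features
#'
#' Keeps the `nTop` features with the largest coefficient of variation
#' (per-feature sd / mean across samples), preserving the original row order
#' among the selected features. Features with mean 0 have no defined CV and
#' are never selected (a message reports how many were excluded). Ties are
#' broken by original row order.
#'
#' @param m An [OmicsMatrix].
#' @param nTop Number of features to keep (at most `nrow(m)`).
#' @return The [OmicsMatrix] restricted to the selected features.
#' @export
selectFeaturesByCV <- function(m, nTop) {
  stopifnot(is(m, "OmicsMatrix"))
  nTop <- .checkCount(nTop, "nTop")
  v <- .values(m)
  if (nTop > nrow(v))
    stop(sprintf("nTop (%d) exceeds the number of features (%d)",
                 nTop, nrow(v)), call. = FALSE)
  mu <- rowMeans(v)
  sdv <- apply(v, 1L, stats::sd)
  cv <- ifelse(mu == 0, -Inf, sdv / mu)
  if (any(mu == 0))
    message(sum(mu == 0), " feature(s) with zero mean excluded from CV ranking")
  ranked <- order(cv, decreasing = TRUE)  # stable: ties keep row order
  keep <- sort(ranked[seq_len(nTop)])
  m[keep, ]
}
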