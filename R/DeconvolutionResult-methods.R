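#' @describeIn DeconvolutionResult Proportion matrix accessor (K x samples).
#' @param x A `DeconvolutionResult`.
#' @export
setMethod("proportions", "DeconvolutionResult", function(x) x@proportions)

#' @describeIn DeconvolutionResult Profile matrix accessor (features x K).
#' @export
setMethod("profiles", "DeconvolutionResult", function(x) x@profiles)

#' @describeIn DeconvolutionResult RSS trace accessor.
#' @export
setMethod("rssTrace", "DeconvolutionResult", function(x) x@rssTrace)

#' @describeIn DeconvolutionResult Engine label accessor.
#' @export
setMethod("engine", "DeconvolutionResult", function(x) x@engine)

#' @describeIn DeconvolutionResult Number of components.
#' @export
setMethod("nComponents", "DeconvolutionResult", function(x) x@K)

#' @describeIn DeconvolutionResult Modality of the deconvolved matrix.
#' @export
setMethod("modality", "DeconvolutionResult", function(x) x@modality)

setMethod("show", "DeconvolutionResult", function(object) {
  cat(sprintf("DeconvolutionResult: engine '%s', K = %d (%s)\n",
              object@engine, object@K, object@modality))
  cat(sprintf("  %d features x %d samples; %d iteration(s)",
              nrow(object@profiles), ncol(object@proportions),
              object@nIterations))
  if (length(object@rssTrace))
    cat(sprintf("; final RSS %.6g", object@rssTrace[length(object@rssTrace)]))
  cat("\n  mean proportions:",
      paste(sprintf("%s=%.3f", rownames(object@proportions),
                    rowMeans(object@proportions)), collapse = " "), "\n")
})

# Internal constructor adding dimnames and validating.
.newResult <- function(A, Tm, engine, modality, rssTrace, nIterations, seed,
                       featureIds, sampleIds, diagnostics = list()) {
  K <- nrow(A)
  dimnames(A) <- list(.componentNames(K), sampleIds)
  dimnames(Tm) <- list(featureIds, .componentNames(K))
  new("DeconvolutionResult",
      proportions = A, profiles = Tm, K = as.integer(K),
      engine = engine, modality = modality,
      rssTrace = as.numeric(rssTrace),
      nIterations = as.integer(nIterations),
      seed = as.integer(seed), diagnostics = diagnostics)
}

#' Match estimated components to ground truth
#'
#' Finds the one-to-one assignment between estimated and true components that
#' maximizes the summed Pearson correlation of proportion rows (optimal
#' assignment, computed exactly by exhaustive search over permutations for
#' K <= 8), then reports per-component correlations and the mean absolute
#' error of the permuted proportions.
#'
#' @param estimated A [DeconvolutionResult] or a K x samples proportion
#'   matrix.
#' @param truthA True K x samples proportion matrix with the same dimensions.
#' @return A list with `permutation` (index of the estimated component
#'   assigned to each true component), `correlations` (per true component),
#'   and `mae`.
#' @examples
#' A <- matrix(c(.7, .3, .2, .8), 2, 2)
#' matchComponents(A[2:1, ], A)$permutation
#' @export
matchComponents <- function(estimated, truthA) {
  A <- if (is(estimated, "DeconvolutionResult")) proportions(estimated)
       else as.matrix(estimated)
  truthA <- as.matrix(truthA)
  if (!identical(dim(A), dim(truthA)))
    stop("estimated and true proportion matrices must have identical dimensions",
         call. = FALSE)
  K <- nrow(A)
  if (K > 8L)
    stop("component matching supports K <= 8", call. = FALSE)
  corMat <- matrix(0, K, K)  # corMat[i, j]: truth row i vs estimate row j
  for (i in seq_len(K)) for (j in seq_len(K)) {
    r <- suppressWarnings(stats::cor(truthA[i, ], A[j, ]))
    corMat[i, j] <- if (is.na(r)) 0 else r
  }
  perms <- .permutations(K)
  sums <- vapply(seq_len(nrow(perms)),
                 function(p) sum(corMat[cbind(seq_len(K), perms[p, ])]),
                 numeric(1))
  best <- perms[which.max(sums), ]
  list(permutation = best,
       correlations = corMat[cbind(seq_len(K), best)],
       mae = mean(abs(A[best, , drop = FALSE] - truthA)))
}

.permutations <- function(K) {
  if (K == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(K - 1L)
  out <- matrix(0L, nrow(sub) * K, K)
  r <- 0L
  for (pos in seq_len(K)) for (i in seq_len(nrow(sub))) {
    r <- r + 1L
    out[r, ] <- append(sub[i, ], K, after = pos - 1L)
  }
  out
}
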