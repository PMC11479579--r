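## Central S4 containers. OmicsMatrix extends SummarizedExperiment so that the
## usual Bioconductor verbs (assay, dim, dimnames, subsetting) work unchanged;
## the only additions are a modality tag and its validity contract.

.MODALITIES <- c("expression", "methylation")
.ENGINES <- c("nmf", "ica", "edec", "cam_lite")

#' OmicsMatrix: a features x samples bulk omics matrix
#'
#' A [SummarizedExperiment::SummarizedExperiment] carrying a single assay
#' named `"values"` (features in rows, samples in columns) plus a modality
#' tag. Expression matrices hold non-negative counts or intensities;
#' methylation matrices hold beta-values, which must lie in \[0, 1\].
#'
#' Feature and sample identifiers (the dimnames) must be present, unique and
#' non-empty; all values must be finite.
#'
#' @slot modality Either `"expression"` or `"methylation"`.
#' @export
setClass("OmicsMatrix",
  contains = "SummarizedExperiment",
  slots = c(modality = "character")
)

setValidity("OmicsMatrix", function(object) {
  msg <- character()
  if (length(object@modality) != 1L || !object@modality %in% .MODALITIES)
    msg <- c(msg, sprintf("modality must be one of: %s",
                          paste(.MODALITIES, collapse = ", ")))
  if (!"values" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'values' is required")
  v <- SummarizedExperiment::assay(object, "values")
  if (!is.numeric(v))
    msg <- c(msg, "assay 'values' must be numeric")
  fid <- rownames(object)
  sid <- colnames(object)
  if (is.null(fid) || anyNA(fid) || any(fid == ""))
    msg <- c(msg, "feature ids (rownames) must be present and non-empty")
  if (is.null(sid) || anyNA(sid) || any(sid == ""))
    msg <- c(msg, "sample ids (colnames) must be present and non-empty")
  if (!is.null(fid) && anyDuplicated(fid))
    msg <- c(msg, sprintf("duplicated feature id(s): %s",
                          paste(unique(fid[duplicated(fid)]), collapse = ", ")))
  if (!is.null(sid) && anyDuplicated(sid))
    msg <- c(msg, sprintf("duplicated sample id(s): %s",
                          paste(unique(sid[duplicated(sid)]), collapse = ", ")))
  if (is.numeric(v) && length(v) && !all(is.finite(v)))
    msg <- c(msg, "all values must be finite (no NA/NaN/Inf)")
  if (identical(object@modality, "methylation") && is.numeric(v) &&
      length(v) && all(is.finite(v)) && (min(v) < 0 || max(v) > 1))
    msg <- c(msg, "methylation beta-values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' DeconvolutionResult: output of a deconvolution engine
#'
#' Holds the factorization X (features x samples) = T (features x K) x
#' A (K x samples) estimated by one of the engines, together with fit
#' diagnostics. Every engine guarantees the simplex constraint on A
#' (entries >= 0, columns summing to 1 within 1e-6) and non-negative T
#' (additionally T <= 1 for methylation).
#'
#' @slot proportions K x samples proportion matrix A.
#' @slot profiles features x K profile matrix T.
#' @slot K Number of components.
#' @slot engine One of `"nmf"`, `"ica"`, `"edec"`, `"cam_lite"`.
#' @slot modality Modality of the input matrix.
#' @slot rssTrace RSS after each outer iteration (non-increasing for the
#'   alternating least-squares engines).
#' @slot nIterations Number of outer iterations run.
#' @slot seed Seed used for the engine's random initialization.
#' @slot diagnostics Engine-specific extras (warnings, size factors, ...).
#' @export
setClass("DeconvolutionResult",
  slots = c(
    proportions = "matrix",
    profiles = "matrix",
    K = "integer",
    engine = "character",
    modality = "character",
    rssTrace = "numeric",
    nIterations = "integer",
    seed = "integer",
    diagnostics = "list"
  )
)

setValidity("DeconvolutionResult", function(object) {
  msg <- character()
  A <- object@proportions
  Tm <- object@profiles
  K <- object@K
  if (length(K) != 1L || is.na(K) || K < 1L)
    msg <- c(msg, "K must be a single positive integer")
  if (!object@engine %in% .ENGINES)
    msg <- c(msg, sprintf("engine must be one of: %s",
                          paste(.ENGINES, collapse = ", ")))
  if (!object@modality %in% .MODALITIES)
    msg <- c(msg, "invalid modality")
  if (nrow(A) != K) msg <- c(msg, "proportions must have K rows")
  if (ncol(Tm) != K) msg <- c(msg, "profiles must have K columns")
  if (length(A)) {
    if (min(A) < -1e-9) msg <- c(msg, "proportions must be non-negative")
    cs <- colSums(A)
    if (any(abs(cs - 1) > 1e-6))
      msg <- c(msg, "proportion columns must sum to 1 (within 1e-6)")
  }
  if (length(Tm)) {
    if (min(Tm) < -1e-9) msg <- c(msg, "profiles must be non-negative")
    if (identical(object@modality, "methylation") && max(Tm) > 1 + 1e-9)
      msg <- c(msg, "methylation profiles must be <= 1")
  }
  if (length(msg)) msg else TRUE
})

#' ScreeResult: PCA-eigenvalue guidance for choosing K
#'
#' @slot eigenvalues Non-increasing, non-negative PCA eigenvalues.
#' @slot varianceExplained Fraction of total variance per eigenvalue.
#' @slot suggestedK Automatic elbow (Cattell-style) suggestion, advisory.
#' @slot centered,scaled Whether features were centered/scaled before PCA.
#' @export
setClass("ScreeResult",
  slots = c(
    eigenvalues = "numeric",
    varianceExplained = "numeric",
    suggestedK = "integer",
    centered = "logical",
    scaled = "logical"
  )
)

setValidity("ScreeResult", function(object) {
  msg <- character()
  ev <- object@eigenvalues
  if (!length(ev)) msg <- c(msg, "eigenvalues must be non-empty")
  if (length(ev) && min(ev) < -1e-9 * max(abs(ev), 1))
    msg <- c(msg, "eigenvalues must be non-negative")
  if (length(ev) > 1 && any(diff(ev) > 1e-9 * max(ev, 1)))
    msg <- c(msg, "eigenvalues must be non-increasing")
  k <- object@suggestedK
  if (length(k) != 1L || is.na(k) || k < 1L || k > length(ev))
    msg <- c(msg, "suggestedK must lie in [1, length(eigenvalues)]")
  if (length(object@varianceExplained) != length(ev))
    msg <- c(msg, "varianceExplained must parallel eigenvalues")
  if (length(msg)) msg else TRUE
})

#' RankedGeneList: per-component gene contribution ranking
#'
#' Gene identifiers sorted by decreasing contribution score; ties are broken
#' lexicographically by gene id so the ranking is deterministic.
#'
#' @slot geneIds Unique gene identifiers, in rank order.
#' @slot scores Parallel numeric scores, non-increasing.
#' @export
setClass("RankedGeneList",
  slots = c(geneIds = "character", scores = "numeric")
)

setValidity("RankedGeneList", function(object) {
  msg <- character()
  if (length(object@geneIds) != length(object@scores))
    msg <- c(msg, "geneIds and scores must have equal length")
  if (anyDuplicated(object@geneIds))
    msg <- c(msg, "geneIds must be unique")
  if (length(object@scores) > 1 && any(diff(object@scores) > 0))
    msg <- c(msg, "scores must be sorted non-increasing")
  if (length(msg)) msg else TRUE
})

#' GeneSetCollection: named gene sets loaded from GMT
#'
#' @slot setList Named list of character vectors (gene ids), each non-empty.
#' @slot descriptions Named character vector parallel to `setList`.
#' @export
setClass("GeneSetCollection",
  slots = c(setList = "list", descriptions = "character")
)

setValidity("GeneSetCollection", function(object) {
  msg <- character()
  nm <- names(object@setList)
  if (is.null(nm) || anyNA(nm) || any(nm == ""))
    msg <- c(msg, "gene sets must be named")
  if (!is.null(nm) && anyDuplicated(nm))
    msg <- c(msg, sprintf("duplicated set name(s): %s",
                          paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  if (any(!vapply(object@setList, is.character, logical(1))) ||
      any(lengths(object@setList) == 0L))
    msg <- c(msg, "each gene set must be a non-empty character vector")
  if (!identical(names(object@descriptions), nm))
    msg <- c(msg, "descriptions must be named like setList")
  if (length(msg)) msg else TRUE
})

#' MixtureTruth: ground truth of a simulated mixture
#'
#' @slot profiles True features x K profile matrix.
#' @slot proportions True K x samples proportion matrix (simplex columns).
#' @slot markerSets Named list of planted marker feature ids per component
#'   (pairwise disjoint).
#' @slot noiseSd Noise level used by the simulator.
#' @slot seed Seed that fully determines the draw.
#' @slot modality Simulated modality.
#' @export
setClass("MixtureTruth",
  slots = c(
    profiles = "matrix",
    proportions = "matrix",
    markerSets = "list",
    noiseSd = "numeric",
    seed = "integer",
    modality = "character"
  )
)

setValidity("MixtureTruth", function(object) {
  msg <- character()
  A <- object@proportions
  if (length(A)) {
    if (min(A) < -1e-9) msg <- c(msg, "true proportions must be non-negative")
    if (any(abs(colSums(A) - 1) > 1e-6))
      msg <- c(msg, "true proportion columns must sum to 1")
  }
  if (ncol(object@profiles) != nrow(A))
    msg <- c(msg, "profiles and proportions disagree on K")
  ms <- unlist(object@markerSets, use.names = FALSE)
  if (anyDuplicated(ms))
    msg <- c(msg, "marker sets must be pairwise disjoint")
  if (identical(object@modality, "methylation") && length(object@profiles) &&
      (min(object@profiles) < 0 || max(object@profiles) > 1))
    msg <- c(msg, "methylation profiles must lie in [0, 1]")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (length(msg)) msg else TRUE
})
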