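#' @include AllClasses.R
NULL

#' Modality of an omics object
#'
#' Returns the omic modality tag, either `"expression"` or `"methylation"`.
#'
#' @param x An [OmicsMatrix], [DeconvolutionResult] or [MixtureTruth] object.
#' @return A length-one character vector.
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))

#' Estimated proportion matrix
#'
#' @param x A [DeconvolutionResult] or [MixtureTruth] object.
#' @return The K x samples proportion matrix A (columns on the simplex).
#' @export
setGeneric("proportions", function(x) standardGeneric("proportions"))

#' Estimated component profile matrix
#'
#' @param x A [DeconvolutionResult] or [MixtureTruth] object.
#' @return The features x K profile matrix T.
#' @export
setGeneric("profiles", function(x) standardGeneric("profiles"))

#' Residual sum-of-squares trace of an iterative engine
#'
#' @param x A [DeconvolutionResult].
#' @return Numeric vector of RSS values, one per outer iteration.
#' @export
setGeneric("rssTrace", function(x) standardGeneric("rssTrace"))

#' Deconvolution engine label
#'
#' @param x A [DeconvolutionResult].
#' @return One of `"nmf"`, `"edec"`, `"ica"`, `"cam_lite"`.
#' @export
setGeneric("engine", function(x) standardGeneric("engine"))

#' Number of components
#'
#' @param x A [DeconvolutionResult], [MixtureTruth] or [ScreeResult].
#' @return Integer number of components K (for `ScreeResult`, the elbow
#'   suggestion).
#' @export
setGeneric("nComponents", function(x) standardGeneric("nComponents"))

#' PCA eigenvalues of a scree analysis
#'
#' @param x A [ScreeResult].
#' @return Non-increasing numeric vector of eigenvalues.
#' @export
setGeneric("eigenvalues", function(x) standardGeneric("eigenvalues"))

#' Gene sets stored in a collection
#'
#' @param x A [GeneSetCollection].
#' @return Named list of character vectors of gene identifiers.
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' Descriptions of the gene sets in a collection
#'
#' @param x A [GeneSetCollection].
#' @return Named character vector of set descriptions.
#' @export
setGeneric("setDescriptions", function(x) standardGeneric("setDescriptions"))

#' Planted marker features of a simulated mixture
#'
#' @param x A [MixtureTruth].
#' @return Named list (one element per component) of marker feature ids.
#' @export
setGeneric("markerSets", function(x) standardGeneric("markerSets"))
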