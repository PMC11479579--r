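#' Construct an OmicsMatrix
#'
#' @param values Numeric matrix, features in rows and samples in columns.
#'   Row and column names are used as feature/sample ids unless `featureIds`
#'   / `sampleIds` are given.
#' @param modality `"expression"` or `"methylation"`.
#' @param featureIds,sampleIds Optional identifier vectors overriding the
#'   dimnames of `values`.
#' @return A validated [OmicsMatrix].
#' @examples
#' m <- OmicsMatrix(matrix(1:6, 3, 2,
#'                         dimnames = list(paste0("g", 1:3), c("s1", "s2"))),
#'                  modality = "expression")
#' modality(m)
#' @export
OmicsMatrix <- function(values, modality = c("expression", "methylation"),
                        featureIds = NULL, sampleIds = NULL) {
  modality <- match.arg(modality)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.null(featureIds)) rownames(values) <- featureIds
  if (!is.null(sampleIds)) colnames(values) <- sampleIds
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(values = values))
  new("OmicsMatrix", se, modality = modality)
}

#' @describeIn OmicsMatrix Modality accessor.
#' @param x An `OmicsMatrix`.
#' @export
setMethod("modality", "OmicsMatrix", function(x) x@modality)

setMethod("show", "OmicsMatrix", function(object) {
  cat(sprintf("OmicsMatrix (%s): %d features x %d samples\n",
              object@modality, nrow(object), ncol(object)))
  v <- .values(object)
  if (length(v))
    cat(sprintf("  value range: [%.4g, %.4g]\n", min(v), max(v)))
  callNextMethod()
})

#' Read a features x samples omics matrix from CSV
#'
#' The expected layout mirrors the common bulk-omics exchange format: the
#' first column holds feature identifiers (genes or CpG probes), the header
#' row holds sample identifiers, every other cell is numeric. Row and column
#' order is preserved. Beta-value matrices (`modality = "methylation"`) are
#' checked to lie in \[0, 1\].
#'
#' @param path Path to a CSV file (comma separator, `.` decimal; the first
#'   header cell is ignored).
#' @param modality `"expression"` or `"methylation"`.
#' @return An [OmicsMatrix].
#' @seealso [writeOmicsCSV()]
#' @export
readOmicsCSV <- function(path, modality = c("expression", "methylation")) {
  modality <- match.arg(modality)
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                        stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (ncol(df) < 2L)
    stop("CSV must have a feature-id column plus at least one sample column",
         call. = FALSE)
  fid <- as.character(df[[1L]])
  sid <- colnames(df)[-1L]
  if (anyDuplicated(fid))
    stop("duplicated feature id(s): ",
         paste(unique(fid[duplicated(fid)]), collapse = ", "), call. = FALSE)
  if (anyDuplicated(sid))
    stop("duplicated sample id(s): ",
         paste(unique(sid[duplicated(sid)]), collapse = ", "), call. = FALSE)
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(vals) || anyNA(vals)) {
    suppressWarnings(num <- matrix(as.numeric(vals), nrow = nrow(vals)))
    bad <- which(is.na(num), arr.ind = TRUE)
    if (nrow(bad) > 0L)
      stop(sprintf("non-numeric value at feature '%s', sample '%s'",
                   fid[bad[1L, 1L]], sid[bad[1L, 2L]]), call. = FALSE)
    vals <- num
  }
  dimnames(vals) <- list(fid, sid)
  if (modality == "methylation" &&
      (min(vals) < 0 || max(vals) > 1)) {
    bad <- which(vals < 0 | vals > 1, arr.ind = TRUE)
    stop(sprintf(
      "beta-value outside [0, 1] at feature '%s', sample '%s' (value %g)",
      fid[bad[1L, 1L]], sid[bad[1L, 2L]], vals[bad[1L, , drop = FALSE]]),
      call. = FALSE)
  }
  OmicsMatrix(vals, modality = modality)
}

#' Write an OmicsMatrix to CSV
#'
#' Inverse of [readOmicsCSV()]: first column `feature_id`, one column per
#' sample. The round trip is lossless to at least 12 significant digits.
#'
#' @param m An [OmicsMatrix].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeOmicsCSV <- function(m, path) {
  stopifnot(is(m, "OmicsMatrix"))
  v <- .values(m)
  df <- data.frame(feature_id = rownames(v),
                   signif(v, 15L),
                   check.names = FALSE, row.names = NULL)
  colnames(df) <- c("feature_id", colnames(v))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
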