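#' Construct a GeneSetCollection
#'
#' @param sets Named list of character vectors of gene identifiers.
#' @param descriptions Optional named character vector of descriptions
#'   (defaults to empty strings).
#' @param minSize Sets with fewer than `minSize` genes are dropped with a
#'   message (default 3, the usual floor for marker-gene sets).
#' @return A [GeneSetCollection].
#' @export
GeneSetCollection <- function(sets, descriptions = NULL, minSize = 3L) {
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("all gene sets must be named", call. = FALSE)
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (is.null(descriptions))
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  descriptions <- descriptions[names(sets)]
  names(descriptions) <- names(sets)
  descriptions[is.na(descriptions)] <- ""
  keep <- lengths(sets) >= minSize
  if (!all(keep))
    message(sum(!keep), " gene set(s) below the minimum size (",
            minSize, ") dropped: ",
            paste(utils::head(names(sets)[!keep], 5L), collapse = ", "))
  if (!any(keep))
    stop("no gene set passes the minimum size filter", call. = FALSE)
  new("GeneSetCollection", setList = sets[keep],
      descriptions = descriptions[keep])
}

#' @describeIn GeneSetCollection Gene-set list accessor.
#' @param x A `GeneSetCollection`.
#' @export
setMethod("geneSets", "GeneSetCollection", function(x) x@setList)

#' @describeIn GeneSetCollection Description accessor.
#' @export
setMethod("setDescriptions", "GeneSetCollection", function(x) x@descriptions)

#' @describeIn GeneSetCollection Number of sets.
#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@setList))

#' @describeIn GeneSetCollection Set names.
#' @export
setMethod("names", "GeneSetCollection", function(x) names(x@setList))

setMethod("show", "GeneSetCollection", function(object) {
  sz <- lengths(object@setList)
  cat(sprintf("GeneSetCollection: %d sets (sizes %d-%d)\n",
              length(sz), min(sz), max(sz)))
  cat("  ", paste(utils::head(names(object@setList), 5L), collapse = ", "),
      if (length(sz) > 5L) ", ..." else "", "\n", sep = "")
})

#' Read gene sets from a GMT file
#'
#' GMT is the tab-separated gene-set exchange format: one set per line, with
#' set name, description, then member gene identifiers. Keeps the
#' description column and applies the minimum-size filter on load.
#'
#' @param path Path to a GMT file.
#' @param minSize Minimum set size retained (default 3).
#' @return A [GeneSetCollection].
#' @seealso [writeGMT()]
#' @export
readGMT <- function(path, minSize = 3L) {
  if (!file.exists(path)) stop("GMT file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop("malformed GMT line (needs name, description, >= 1 gene): line ",
         short[1L], call. = FALSE)
  nm <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nm))
    stop("duplicated set name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  desc <- stats::setNames(vapply(fields, `[[`, character(1), 2L), nm)
  sets <- stats::setNames(
    lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])])), nm)
  GeneSetCollection(sets, desc, minSize = minSize)
}

#' Write a GeneSetCollection to GMT
#'
#' @param x A [GeneSetCollection].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeGMT <- function(x, path) {
  stopifnot(is(x, "GeneSetCollection"))
  lines <- vapply(names(x), function(nm) {
    paste(c(nm, x@descriptions[[nm]], x@setList[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
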