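#' Rank genes by their contribution to a component
#'
#' Sorts the features by the chosen column of the profile matrix T,
#' descending; ties are broken lexicographically (C locale) by gene id so
#' the ranking is deterministic.
#'
#' @param x A [DeconvolutionResult] or a features x K profile matrix with
#'   rownames.
#' @param component Component index in `1..K`.
#' @return A [RankedGeneList].
#' @export
rankComponentGenes <- function(x, component) {
  Tm <- if (is(x, "DeconvolutionResult")) profiles(x) else as.matrix(x)
  component <- .checkCount(component, "component")
  if (component > ncol(Tm))
    stop(sprintf("component %d out of range (K = %d)", component, ncol(Tm)),
         call. = FALSE)
  if (is.null(rownames(Tm)))
    stop("profile matrix must have feature ids as rownames", call. = FALSE)
  .rankedGeneList(stats::setNames(Tm[, component], rownames(Tm)))
}

# Named score vector -> RankedGeneList (desc score, ties lexicographic).
.rankedGeneList <- function(scores) {
  ids <- names(scores)
  ord <- order(-scores, ids, method = "radix")
  new("RankedGeneList", geneIds = ids[ord],
      scores = unname(scores[ord]))
}

#' @describeIn rankComponentGenes Length of a ranking.
#' @param x A `RankedGeneList`.
#' @export
setMethod("length", "RankedGeneList", function(x) length(x@geneIds))

setMethod("show", "RankedGeneList", function(object) {
  cat(sprintf("RankedGeneList: %d genes\n", length(object@geneIds)))
  n <- min(5L, length(object@geneIds))
  cat("  top:", paste(sprintf("%s (%.4g)", object@geneIds[seq_len(n)],
                              object@scores[seq_len(n)]), collapse = ", "),
      "\n")
})

#' Gene ids of a ranking, in rank order
#' @param x A [RankedGeneList].
#' @return Character vector.
#' @export
geneIds <- function(x) { stopifnot(is(x, "RankedGeneList")); x@geneIds }

#' Scores of a ranking, in rank order
#' @param x A [RankedGeneList].
#' @return Numeric vector.
#' @export
geneScores <- function(x) { stopifnot(is(x, "RankedGeneList")); x@scores }

#' Aggregate CpG-level scores to gene level
#'
#' A gene's component score is the maximum score over its CpGs, so a gene
#' counts as strongly contributing if at least one of its CpGs does. CpGs
#' absent from the map are dropped (their count is reported in a message).
#'
#' @param scores Named numeric vector of per-CpG scores.
#' @param cpgMap Data frame (or named character vector) mapping CpG id to
#'   gene id; as a data frame, the first column is the CpG id and the second
#'   the gene id.
#' @return Named numeric vector of per-gene scores.
#' @export
aggregateCpgScores <- function(scores, cpgMap) {
  if (is.null(names(scores))) stop("scores must be named by CpG id",
                                   call. = FALSE)
  map <- if (is.data.frame(cpgMap))
    stats::setNames(as.character(cpgMap[[2L]]), as.character(cpgMap[[1L]]))
  else cpgMap
  genes <- map[names(scores)]
  unmapped <- is.na(genes)
  if (any(unmapped))
    message(sum(unmapped), " CpG(s) without a gene mapping dropped")
  if (all(unmapped))
    stop("no CpG could be mapped to a gene", call. = FALSE)
  s <- scores[!unmapped]
  g <- genes[!unmapped]
  out <- vapply(split(s, g), max, numeric(1))
  out[unique(g)]   # keep first-appearance gene order
}

#' Choose between GSEA and ORA for a component
#'
#' Preranked GSEA needs enough distinct values to order genes reliably; if
#' the fraction of distinct score values is at least `nondupThreshold`
#' (default 30%), GSEA is chosen, otherwise ORA. The boundary is inclusive.
#'
#' @param scores Numeric vector of contribution scores.
#' @param nondupThreshold Minimum distinct-value fraction for GSEA
#'   (default 0.30).
#' @return `"GSEA"` or `"ORA"`.
#' @export
chooseEnrichmentMethod <- function(scores, nondupThreshold = 0.30) {
  if (!length(scores)) stop("empty score vector", call. = FALSE)
  frac <- length(unique(scores)) / length(scores)
  if (frac >= nondupThreshold) "GSEA" else "ORA"
}

# Enrichment score of the weighted Kolmogorov-Smirnov running sum, computed
# from the sorted in-set positions only (O(n log n) rather than O(N)).
# Scanning the ranking, the sum gains |score|^p / sum(|score|^p in set) at
# members and loses 1/(N - n) at non-members; ES is the maximum deviation
# from zero (positive deviations win ties, deterministically).
.gseaES <- function(absWeights, positions, weightP = 1) {
  N <- length(absWeights)
  n <- length(positions)
  pos <- sort(positions)
  r <- absWeights[pos]^weightP
  hit <- cumsum(r) / sum(r)
  miss <- 1 / (N - n)
  atHit <- hit - miss * (pos - seq_len(n))          # just after each member
  beforeHit <- c(0, hit[-n]) - miss * (pos - seq_len(n))  # just before
  maxPos <- max(atHit)
  minNeg <- min(beforeHit, hit[n] - miss * (N - n)) # includes scan end
  if (maxPos >= -minNeg) maxPos else minNeg
}

#' Preranked gene-set enrichment analysis
#'
#' Computes, for each gene set, the weighted Kolmogorov-Smirnov enrichment
#' score (ES) over the ranked gene list: scanning the ranking from top to
#' bottom, a running sum gains `|score|^weightP` (normalized) at set members
#' and loses `1/(N - n)` at non-members; ES is the maximum deviation from
#' zero. Significance comes from a permutation null: `nPerm` random gene
#' sets of the same size are drawn from the ranking, and
#' `p = (1 + #same-sign null ES at least as extreme) / (1 + #same-sign null
#' ES)`, one-sided on the sign of the observed ES (never exactly 0 thanks to
#' the +1 correction). P-values are Benjamini-Hochberg adjusted across the
#' sets tested.
#'
#' @param ranked A [RankedGeneList] covering the analysis universe (all
#'   genes of the user's matrix).
#' @param sets A [GeneSetCollection]; each set is intersected with the
#'   universe, and sets smaller than `minSize` afterwards are skipped with a
#'   message.
#' @param nPerm Number of null permutations (default 1000).
#' @param seed Integer seed for the permutation draws, or `NULL` to use the
#'   current RNG stream.
#' @param weightP Weighting exponent of the running sum (default 1).
#' @param minSize Minimum post-intersection set size (default 3).
#' @return A data.frame with columns `set`, `method`, `statistic` (ES),
#'   `overlap` (set size in the universe), `p_value`, `p_adjusted`, sorted
#'   by `p_adjusted`.
#' @export
gseaPreranked <- function(ranked, sets, nPerm = 1000L, seed = NULL,
                          weightP = 1, minSize = 3L) {
  stopifnot(is(ranked, "RankedGeneList"), is(sets, "GeneSetCollection"))
  nPerm <- .checkCount(nPerm, "nPerm")
  universe <- ranked@geneIds
  N <- length(universe)
  absW <- abs(ranked@scores)
  .withSeed(seed, {
    rows <- lapply(names(sets), function(nm) {
      members <- which(universe %in% sets@setList[[nm]])
      n <- length(members)
      if (n < minSize) {
        message("set '", nm, "' has fewer than ", minSize,
                " genes in the universe; skipped")
        return(NULL)
      }
      if (n >= N) {
        message("set '", nm, "' covers the whole universe; skipped")
        return(NULL)
      }
      es <- .gseaES(absW, members, weightP)
      null <- vapply(seq_len(nPerm), function(i)
        .gseaES(absW, sample.int(N, n), weightP), numeric(1))
      if (es >= 0) {
        side <- null[null >= 0]
        p <- (1 + sum(side >= es)) / (1 + length(side))
      } else {
        side <- null[null < 0]
        p <- (1 + sum(side <= es)) / (1 + length(side))
      }
      data.frame(set = nm, method = "GSEA", statistic = es,
                 overlap = n, p_value = p, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
      stop("no gene set could be tested against the ranking", call. = FALSE)
    out$p_adjusted <- adjustBH(out$p_value)
    out[order(out$p_adjusted, out$p_value, out$set), , drop = FALSE]
  })
}

#' Over-representation analysis (hypergeometric test)
#'
#' Takes the top `topFraction` of the ranking (ceiling of
#' `topFraction * N`) as the selection and the whole ranking as the
#' universe, then tests each gene set for over-representation in the
#' selection with the hypergeometric upper tail
#' `P(overlap >= observed)`. The statistic is the sample odds ratio of the
#' 2x2 selection-by-membership table. P-values are Benjamini-Hochberg
#' adjusted across the sets tested.
#'
#' @param ranked A [RankedGeneList] (the universe).
#' @param sets A [GeneSetCollection].
#' @param topFraction Fraction of the ranking selected (default 0.20).
#' @param minSize Minimum post-intersection set size (default 3).
#' @return A data.frame with columns `set`, `method`, `statistic` (odds
#'   ratio), `overlap`, `p_value`, `p_adjusted`, sorted by `p_adjusted`.
#' @export
oraEnrichment <- function(ranked, sets, topFraction = 0.20, minSize = 3L) {
  stopifnot(is(ranked, "RankedGeneList"), is(sets, "GeneSetCollection"))
  if (!is.numeric(topFraction) || topFraction <= 0 || topFraction >= 1)
    stop("topFraction must lie strictly between 0 and 1", call. = FALSE)
  universe <- ranked@geneIds
  N <- length(universe)
  selSize <- as.integer(ceiling(topFraction * N))
  selection <- universe[seq_len(selSize)]
  rows <- lapply(names(sets), function(nm) {
    inUniverse <- intersect(sets@setList[[nm]], universe)
    sz <- length(inUniverse)
    if (sz < minSize) {
      message("set '", nm, "' has fewer than ", minSize,
              " genes in the universe; skipped")
      return(NULL)
    }
    a <- length(intersect(inUniverse, selection))
    b <- selSize - a
    cc <- sz - a
    d <- N - selSize - cc
    p <- stats::phyper(a - 1L, sz, N - sz, selSize, lower.tail = FALSE)
    or <- if (b * cc == 0) {
      if (a * d == 0) NaN else Inf
    } else (a * d) / (b * cc)
    data.frame(set = nm, method = "ORA", statistic = or,
               overlap = a, p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    stop("no gene set overlaps the universe", call. = FALSE)
  out$p_adjusted <- adjustBH(out$p_value)
  out[order(out$p_adjusted, out$p_value, out$set), , drop = FALSE]
}

#' Benjamini-Hochberg adjustment
#'
#' Validated wrapper around `stats::p.adjust(method = "BH")` (step-up false
#' discovery rate control, monotone, clipped to 1).
#'
#' @param pValues Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values, elementwise >= the raw values.
#' @export
adjustBH <- function(pValues) {
  if (!is.numeric(pValues) || anyNA(pValues) ||
      any(pValues < 0 | pValues > 1))
    stop("p-values must be numeric in [0, 1]", call. = FALSE)
  stats::p.adjust(pValues, method = "BH")
}

#' Biological interpretation of deconvolved components
#'
#' For every component of a deconvolution result: rank the features by their
#' component coordinate (aggregating CpG scores to genes by the max rule
#' first for methylation data, and reorienting weight columns first for the
#' ICA engine), choose GSEA or ORA by the distinct-value rule
#' ([chooseEnrichmentMethod()]), run the chosen test against the gene-set
#' collection, then pool all results and re-apply the Benjamini-Hochberg
#' adjustment within each method pool.
#'
#' @param result A [DeconvolutionResult].
#' @param sets A [GeneSetCollection].
#' @param cpgMap CpG-to-gene map (required iff the result is methylation);
#'   see [aggregateCpgScores()].
#' @param nPerm Permutations for GSEA components (default 1000).
#' @param seed Integer seed (one stream shared by all components).
#' @param nondupThreshold,topFraction,weightP,minSize Passed to the
#'   dispatch, ORA and GSEA steps.
#' @return A data.frame with columns `component`, `set`, `method`,
#'   `statistic`, `overlap`, `p_value`, `p_adjusted`, sorted by
#'   `p_adjusted`.
#' @export
interpretComponents <- function(result, sets, cpgMap = NULL, nPerm = 1000L,
                                seed = 1L, nondupThreshold = 0.30,
                                topFraction = 0.20, weightP = 1,
                                minSize = 3L) {
  stopifnot(is(result, "DeconvolutionResult"), is(sets, "GeneSetCollection"))
  if (modality(result) == "methylation" && is.null(cpgMap))
    stop("methylation results require a cpgMap to aggregate CpGs to genes",
         call. = FALSE)
  Tm <- profiles(result)
  if (engine(result) == "ica")
    Tm <- reorientComponents(Tm)$weights
  K <- nComponents(result)
  .withSeed(seed, {
    rows <- lapply(seq_len(K), function(k) {
      scores <- stats::setNames(Tm[, k], rownames(Tm))
      if (modality(result) == "methylation")
        scores <- aggregateCpgScores(scores, cpgMap)
      ranked <- .rankedGeneList(scores)
      method <- chooseEnrichmentMethod(ranked@scores, nondupThreshold)
      res <- if (method == "GSEA")
        gseaPreranked(ranked, sets, nPerm = nPerm, seed = NULL,
                      weightP = weightP, minSize = minSize)
      else
        oraEnrichment(ranked, sets, topFraction = topFraction,
                      minSize = minSize)
      cbind(component = k, res)
    })
    out <- do.call(rbind, rows)
    for (meth in unique(out$method)) {  # re-adjust across pooled tests
      sel <- out$method == meth
      out$p_adjusted[sel] <- adjustBH(out$p_value[sel])
    }
    rownames(out) <- NULL
    out[order(out$p_adjusted, out$p_value, out$component, out$set), ,
        drop = FALSE]
  })
}
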