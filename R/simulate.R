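#' @describeIn MixtureTruth True proportions accessor.
#' @param x A `MixtureTruth`.
#' @export
setMethod("proportions", "MixtureTruth", function(x) x@proportions)

#' @describeIn MixtureTruth True profiles accessor.
#' @export
setMethod("profiles", "MixtureTruth", function(x) x@profiles)

#' @describeIn MixtureTruth Planted marker sets accessor.
#' @export
setMethod("markerSets", "MixtureTruth", function(x) x@markerSets)

#' @describeIn MixtureTruth Modality of the simulated matrix.
#' @export
setMethod("modality", "MixtureTruth", function(x) x@modality)

#' @describeIn MixtureTruth Number of simulated components.
#' @export
setMethod("nComponents", "MixtureTruth", function(x) nrow(x@proportions))

setMethod("show", "MixtureTruth", function(object) {
  cat(sprintf("MixtureTruth (%s): K = %d, %d features x %d samples, noiseSd = %g, seed = %d\n",
              object@modality, nrow(object@proportions),
              nrow(object@profiles), ncol(object@proportions),
              object@noiseSd, object@seed))
})

# Overwrite the leading columns of A with vertex (purified-sample) columns,
# pureSamples per component, cycling through components.
.plantPureSamples <- function(A, pureSamples) {
  pureSamples <- .checkCount(pureSamples, "pureSamples", 0L)
  nPure <- pureSamples * nrow(A)
  if (nPure == 0L) return(A)
  if (nPure > ncol(A))
    stop("pureSamples * K exceeds the number of samples", call. = FALSE)
  for (j in seq_len(nPure)) {
    A[, j] <- 0
    A[(j - 1L) %% nrow(A) + 1L, j] <- 1
  }
  A
}

# Dirichlet(alpha,...,alpha) columns.
.rdirichlet <- function(K, n, alpha = 1) {
  E <- matrix(stats::rgamma(K * n, shape = alpha, rate = 1), nrow = K)
  E[E == 0] <- .Machine$double.xmin
  sweep(E, 2L, colSums(E), "/")
}

#' Simulate a bulk expression mixture with planted markers
#'
#' Generates a cohort of bulk expression profiles mixing K latent cell types
#' in Dirichlet-distributed proportions, in the spirit of designed
#' cell-line/immune-cell mixture benchmarks. Cell-type profiles have a
#' shared log-normal baseline per gene (meanlog 5, sdlog 1, a realistic
#' spread of expression magnitudes), mild per-type log-normal variation, and
#' `nMarkersPerComponent` planted marker genes per component, up-weighted by
#' `foldChange` in their component only. The observed matrix is
#' `X = T A` with multiplicative log-normal noise
#' (`X * exp(rnorm(sd = noiseSd))`). Fully determined by `seed`.
#'
#' @param K Number of components.
#' @param nFeatures,nSamples Matrix dimensions.
#' @param nMarkersPerComponent Planted markers per component
#'   (`K * nMarkersPerComponent <= nFeatures`).
#' @param noiseSd Log-scale standard deviation of the multiplicative noise
#'   (0 = noiseless).
#' @param seed Integer seed.
#' @param foldChange Marker up-weighting factor (default 8).
#' @param dirichletAlpha Concentration of the proportion prior (default 1,
#'   uniform on the simplex).
#' @param pureMarkers If `TRUE`, marker genes are expressed exclusively in
#'   their own component (zero elsewhere), the "perfect marker" regime of
#'   exact-recovery benchmarks; by default markers keep a baseline level in
#'   the other components.
#' @param pureSamples Number of purified (vertex) samples included per
#'   component: the first `K * pureSamples` columns are pure single-type
#'   samples, mirroring designed mixture benchmarks that profile the
#'   purified constituents alongside the mixtures. Default 0 (all columns
#'   Dirichlet mixtures). Exact recovery of proportions is only identifiable
#'   when the cohort covers the simplex vertices.
#' @return A list with `matrix` (an expression [OmicsMatrix]) and `truth`
#'   (a [MixtureTruth] whose `markerSets` name the planted marker genes).
#' @examples
#' sim <- simulateExpressionMixture(K = 2, nFeatures = 100, nSamples = 10,
#'                                  nMarkersPerComponent = 5, noiseSd = 0,
#'                                  seed = 1)
#' dim(sim$matrix)
#' @export
simulateExpressionMixture <- function(K, nFeatures, nSamples,
                                      nMarkersPerComponent, noiseSd, seed,
                                      foldChange = 8, dirichletAlpha = 1,
                                      pureMarkers = FALSE, pureSamples = 0L) {
  K <- .checkCount(K, "K")
  nFeatures <- .checkCount(nFeatures, "nFeatures", 2L)
  nSamples <- .checkCount(nSamples, "nSamples", 2L)
  nMarkersPerComponent <- .checkCount(nMarkersPerComponent,
                                      "nMarkersPerComponent", 0L)
  if (K * nMarkersPerComponent > nFeatures)
    stop("marker capacity exceeded: K * nMarkersPerComponent > nFeatures",
         call. = FALSE)
  if (noiseSd < 0) stop("noiseSd must be >= 0", call. = FALSE)
  seed <- .checkSeed(seed)
  .withSeed(seed, {
    fid <- sprintf("g%05d", seq_len(nFeatures))
    sid <- sprintf("s%03d", seq_len(nSamples))
    baseline <- stats::rlnorm(nFeatures, meanlog = 5, sdlog = 1)
    Tm <- baseline * matrix(stats::rlnorm(nFeatures * K, 0, 0.25),
                            nFeatures, K)
    markers <- vector("list", K)
    for (k in seq_len(K)) {
      idx <- ((k - 1L) * nMarkersPerComponent) + seq_len(nMarkersPerComponent)
      Tm[idx, k] <- Tm[idx, k] * foldChange    # up-weighted in component k only
      if (pureMarkers) Tm[idx, -k] <- 0
      markers[[k]] <- fid[idx]
    }
    names(markers) <- .componentNames(K)
    A <- .rdirichlet(K, nSamples, dirichletAlpha)
    A <- .plantPureSamples(A, pureSamples)
    X <- Tm %*% A
    if (noiseSd > 0)
      X <- X * exp(matrix(stats::rnorm(length(X), 0, noiseSd), nrow(X)))
    dimnames(X) <- list(fid, sid)
    dimnames(Tm) <- list(fid, .componentNames(K))
    dimnames(A) <- list(.componentNames(K), sid)
    list(matrix = OmicsMatrix(X, modality = "expression"),
         truth = new("MixtureTruth", profiles = Tm, proportions = A,
                     markerSets = markers, noiseSd = noiseSd, seed = seed,
                     modality = "expression"))
  })
}

#' Simulate a bulk methylation (beta-value) mixture
#'
#' Generates reconstituted-mixture-style methylation data: cell-type CpG
#' profiles drawn from Beta(0.3, 0.3) (the bimodal distribution typical of
#' beta-values), plus `nAnchorCpgs` anchor CpGs per component
#' (beta = 0.95 in their component, 0.05 elsewhere). The observed matrix is
#' `T A` plus additive Gaussian noise, clipped to \[0, 1\]. Anchor blocks
#' are aligned to genes (3 CpGs per synthetic gene) so each component's
#' anchor genes are disjoint; the returned `cpgMap` assigns every CpG to a
#' gene for [aggregateCpgScores()].
#'
#' @param K Number of components.
#' @param nFeatures,nSamples Matrix dimensions.
#' @param nAnchorCpgs Anchor CpGs per component.
#' @param noiseSd Standard deviation of the additive noise before clipping.
#' @param seed Integer seed.
#' @param dirichletAlpha Concentration of the proportion prior (default 1).
#' @param pureSamples Purified (vertex) samples per component placed in the
#'   leading columns, as in [simulateExpressionMixture()] (default 0).
#' @return A list with `matrix` (a methylation [OmicsMatrix]), `truth` (a
#'   [MixtureTruth] whose `markerSets` name the anchor *genes*), and
#'   `cpgMap` (data.frame with columns `cpg`, `gene`).
#' @export
simulateMethylationMixture <- function(K, nFeatures, nSamples, nAnchorCpgs,
                                       noiseSd, seed, dirichletAlpha = 1,
                                       pureSamples = 0L) {
  K <- .checkCount(K, "K")
  nFeatures <- .checkCount(nFeatures, "nFeatures", 2L)
  nSamples <- .checkCount(nSamples, "nSamples", 2L)
  nAnchorCpgs <- .checkCount(nAnchorCpgs, "nAnchorCpgs", 1L)
  if (noiseSd < 0) stop("noiseSd must be >= 0", call. = FALSE)
  # anchor blocks padded to multiples of 3 so they align with gene triples
  blockLen <- as.integer(ceiling(nAnchorCpgs / 3) * 3)
  if (K * blockLen > nFeatures)
    stop("anchor capacity exceeded: need K * ceiling(nAnchorCpgs/3)*3 <= nFeatures",
         call. = FALSE)
  seed <- .checkSeed(seed)
  .withSeed(seed, {
    fid <- sprintf("cg%06d", seq_len(nFeatures))
    sid <- sprintf("s%03d", seq_len(nSamples))
    gene <- sprintf("gene%05d", (seq_len(nFeatures) - 1L) %/% 3L + 1L)
    Tm <- matrix(stats::rbeta(nFeatures * K, 0.3, 0.3), nFeatures, K)
    markers <- vector("list", K)
    for (k in seq_len(K)) {
      idx <- ((k - 1L) * blockLen) + seq_len(nAnchorCpgs)
      Tm[idx, ] <- 0.05
      Tm[idx, k] <- 0.95
      markers[[k]] <- unique(gene[idx])
    }
    names(markers) <- .componentNames(K)
    A <- .rdirichlet(K, nSamples, dirichletAlpha)
    A <- .plantPureSamples(A, pureSamples)
    X <- Tm %*% A
    if (noiseSd > 0)
      X <- X + matrix(stats::rnorm(length(X), 0, noiseSd), nrow(X))
    X[X < 0] <- 0
    X[X > 1] <- 1
    dimnames(X) <- list(fid, sid)
    dimnames(Tm) <- list(fid, .componentNames(K))
    dimnames(A) <- list(.componentNames(K), sid)
    list(matrix = OmicsMatrix(X, modality = "methylation"),
         truth = new("MixtureTruth", profiles = Tm, proportions = A,
                     markerSets = markers, noiseSd = noiseSd, seed = seed,
                     modality = "methylation"),
         cpgMap = data.frame(cpg = fid, gene = gene,
                             stringsAsFactors = FALSE))
  })
}
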