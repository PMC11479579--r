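#' Assemble a pipeline run configuration
#'
#' A `RunConfig` is a validated named list capturing every choice of a full
#' run — input paths, modality, preprocessing, engine, K, seed, enrichment
#' parameters — so that runs are reproducible from a single YAML file.
#'
#' @param input Path to the input matrix CSV (see [readOmicsCSV()]).
#' @param outputDir Directory receiving all outputs (created if absent).
#' @param modality `"expression"` or `"methylation"`.
#' @param engine Deconvolution engine (see [deconvolve()]).
#' @param K Number of components.
#' @param seed Integer seed used for every stochastic stage.
#' @param normalize `"none"`, `"rpm"` or `"mor"` (median-of-ratios);
#'   expression only.
#' @param transform `"none"`, `"log2"` or `"pseudoLog"`; expression only.
#' @param topFeatures Number of features kept by CV selection (`NULL` = keep
#'   all).
#' @param gmt Optional path to a GMT file; enables the interpretation stage.
#' @param cpgMap Optional path to a CpG-to-gene CSV (columns cpg, gene);
#'   required with `gmt` for methylation runs.
#' @param nPerm GSEA permutations (default 1000).
#' @param topGenes Number of top contributing genes written per component
#'   (default 100).
#' @return A `RunConfig` object (named list).
#' @seealso [runPipeline()], [readRunConfig()], [writeRunConfig()]
#' @export
RunConfig <- function(input, outputDir, modality = "expression",
                      engine = "nmf", K = 2L, seed = 1L,
                      normalize = "none", transform = "none",
                      topFeatures = NULL, gmt = NULL, cpgMap = NULL,
                      nPerm = 1000L, topGenes = 100L) {
  cfg <- list(
    input = as.character(input),
    outputDir = as.character(outputDir),
    modality = match.arg(modality, c("expression", "methylation")),
    engine = match.arg(engine, c("nmf", "ica", "edec", "cam_lite")),
    K = .checkCount(K, "K"),
    seed = .checkSeed(seed),
    normalize = match.arg(normalize, c("none", "rpm", "mor")),
    transform = match.arg(transform, c("none", "log2", "pseudoLog")),
    topFeatures = if (is.null(topFeatures)) NULL
                  else .checkCount(topFeatures, "topFeatures"),
    gmt = if (is.null(gmt)) NULL else as.character(gmt),
    cpgMap = if (is.null(cpgMap)) NULL else as.character(cpgMap),
    nPerm = .checkCount(nPerm, "nPerm"),
    topGenes = .checkCount(topGenes, "topGenes"))
  if (cfg$modality == "methylation" &&
      (cfg$normalize != "none" || cfg$transform != "none"))
    stop("normalization/transformation apply to expression data only",
         call. = FALSE)
  structure(cfg, class = "RunConfig")
}

#' Read a RunConfig from YAML
#'
#' @param path YAML file written by [writeRunConfig()] (or by hand).
#' @return A `RunConfig`.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  do.call(RunConfig, raw)
}

#' Write a RunConfig to YAML
#'
#' The file round-trips losslessly through [readRunConfig()].
#'
#' @param config A `RunConfig`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeRunConfig <- function(config, path) {
  stopifnot(inherits(config, "RunConfig"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full deconvolution pipeline
#'
#' Chains every stage from one config: read the input CSV, preprocess
#' (normalize, transform, CV feature selection), compute the scree guidance,
#' deconvolve with the configured engine, and (when a GMT is supplied)
#' interpret the components. All artifacts a downstream user needs are
#' written to `outputDir`:
#' \itemize{
#'   \item `preprocessed.csv` — matrix after preprocessing
#'   \item `scree.csv` — eigenvalue table with the elbow suggestion
#'   \item `proportions.csv` — estimated A (K x samples)
#'   \item `profiles.csv` — estimated T (features x K)
#'   \item `top_genes.csv` — top contributing genes per component
#'   \item `enrichment.csv` — enrichment table (when a GMT is given)
#'   \item `diagnostics.json` — engine, K, seed, RSS trace, resolved config
#'   \item `run.log` — per-stage log
#' }
#' Reruns with the same config and seed are byte-identical (apart from
#' timestamps in the log).
#'
#' @param config A `RunConfig` or path to a YAML config.
#' @return Invisibly, a named list of output file paths (plus the
#'   [DeconvolutionResult] under `$result`).
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(config$outputDir, "run.log")
  logCon <- file(logPath, open = "wt")
  on.exit(close(logCon))
  logMsg <- function(...) {
    writeLines(paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ...), logCon)
  }
  stage <- function(name, expr) {
    logMsg("stage ", name, " started")
    out <- tryCatch(expr, error = function(e) {
      logMsg("stage ", name, " FAILED: ", conditionMessage(e))
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    logMsg("stage ", name, " done")
    out
  }
  logMsg("resolved config: ",
         jsonlite::toJSON(unclass(config), auto_unbox = TRUE, null = "null"))
  paths <- list(log = logPath)

  m <- stage("load", readOmicsCSV(config$input, config$modality))
  m <- stage("preprocess", {
    if (config$normalize == "rpm") m <- normalizeRPM(m)
    if (config$normalize == "mor") m <- normalizeMedianOfRatios(m)$matrix
    if (config$transform != "none") m <- transformValues(m, config$transform)
    if (!is.null(config$topFeatures))
      m <- selectFeaturesByCV(m, config$topFeatures)
    m
  })
  paths$preprocessed <- file.path(config$outputDir, "preprocessed.csv")
  writeOmicsCSV(m, paths$preprocessed)

  sc <- stage("estimate-k", scree(m))
  paths$scree <- file.path(config$outputDir, "scree.csv")
  utils::write.csv(
    data.frame(component = seq_along(eigenvalues(sc)),
               eigenvalue = eigenvalues(sc),
               variance_fraction = varianceExplained(sc),
               suggested_k = nComponents(sc)),
    paths$scree, row.names = FALSE)

  fit <- stage("deconvolve",
               deconvolve(m, config$K, config$engine, config$seed))
  A <- proportions(fit)
  Tm <- profiles(fit)
  paths$proportions <- file.path(config$outputDir, "proportions.csv")
  utils::write.csv(data.frame(component = rownames(A), A,
                              check.names = FALSE),
                   paths$proportions, row.names = FALSE)
  paths$profiles <- file.path(config$outputDir, "profiles.csv")
  utils::write.csv(data.frame(feature_id = rownames(Tm), Tm,
                              check.names = FALSE),
                   paths$profiles, row.names = FALSE)

  topGenes <- stage("top-genes", {
    do.call(rbind, lapply(seq_len(nComponents(fit)), function(k) {
      r <- rankComponentGenes(fit, k)
      n <- min(config$topGenes, length(r))
      data.frame(component = k, rank = seq_len(n),
                 gene = geneIds(r)[seq_len(n)],
                 score = geneScores(r)[seq_len(n)])
    }))
  })
  paths$topGenes <- file.path(config$outputDir, "top_genes.csv")
  utils::write.csv(topGenes, paths$topGenes, row.names = FALSE)

  if (!is.null(config$gmt)) {
    enr <- stage("interpret", {
      sets <- readGMT(config$gmt)
      cpgMap <- if (!is.null(config$cpgMap))
        utils::read.csv(config$cpgMap, stringsAsFactors = FALSE) else NULL
      interpretComponents(fit, sets, cpgMap = cpgMap,
                          nPerm = config$nPerm, seed = config$seed)
    })
    paths$enrichment <- file.path(config$outputDir, "enrichment.csv")
    utils::write.csv(enr, paths$enrichment, row.names = FALSE)
  }

  paths$diagnostics <- file.path(config$outputDir, "diagnostics.json")
  diag <- list(engine = engine(fit), K = nComponents(fit),
               seed = config$seed, nIterations = fit@nIterations,
               rssTrace = rssTrace(fit),
               suggestedK = nComponents(sc),
               config = unclass(config))
  jsonlite::write_json(diag, paths$diagnostics, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  logMsg("pipeline complete")
  paths$result <- fit
  invisible(paths)
}
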