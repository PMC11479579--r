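test_that("gene ranking sorts by component coordinate with lexicographic ties", {
  Tm <- cbind(C1 = c(a = 1, b = 3, c = 2), C2 = c(a = 2, b = 2, c = 2))
  r1 <- rankComponentGenes(Tm, 1)
  expect_identical(geneIds(r1), c("b", "c", "a"))
  expect_identical(geneScores(r1), c(3, 2, 1))
  r2 <- rankComponentGenes(Tm, 2)
  expect_identical(geneIds(r2), c("a", "b", "c"))  # tie rule
  expect_error(rankComponentGenes(Tm, 3), "out of range")
})

test_that("CpG aggregation takes the per-gene maximum", {
  scores <- c(cg1 = 0.1, cg2 = 0.9, cg3 = 0.4, cg4 = 0.7)
  map <- data.frame(cpg = c("cg1", "cg2", "cg3", "cg4"),
                    gene = c("G1", "G1", "G1", "G2"))
  out <- aggregateCpgScores(scores, map)
  expect_equal(out, c(G1 = 0.9, G2 = 0.7))
  # one CpG per gene: identity on scores
  map1 <- data.frame(cpg = names(scores), gene = paste0("u", 1:4))
  expect_equal(unname(aggregateCpgScores(scores, map1)), unname(scores))
  # unmapped CpGs are dropped with a message; empty result errors
  expect_message(aggregateCpgScores(scores, map[1:2, ]), "dropped")
  expect_error(suppressMessages(
    aggregateCpgScores(scores, data.frame(cpg = "zz", gene = "G"))),
    "no CpG")
})

test_that("CpG aggregation equals a brute-force group-by max on random data", {
  set.seed(91)
  cpgs <- sprintf("cg%03d", 1:200)
  genes <- sample(sprintf("G%02d", 1:40), 200, replace = TRUE)
  scores <- setNames(rnorm(200), cpgs)
  out <- aggregateCpgScores(scores, data.frame(cpg = cpgs, gene = genes))
  oracle <- tapply(scores, genes, max)
  oracle <- setNames(as.numeric(oracle), names(oracle))
  expect_equal(out[sort(names(out))], oracle[sort(names(oracle))])
})

test_that("method dispatch follows the 30% distinct-value rule inclusively", {
  expect_identical(chooseEnrichmentMethod(rnorm(100)), "GSEA")
  expect_identical(chooseEnrichmentMethod(rep(1:10, each = 10)), "ORA")
  # exactly at the boundary: 30 distinct of 100 -> GSEA
  expect_identical(chooseEnrichmentMethod(c(1:30, rep(1, 70))), "GSEA")
  expect_identical(chooseEnrichmentMethod(c(1:29, rep(1, 71))), "ORA")
})

test_that("GSEA enrichment score matches the naive running sum and fgsea", {
  scores <- c(g01 = 5, g02 = 4, g03 = 3.5, g04 = 3, g05 = 2,
              g06 = 1.5, g07 = 1, g08 = 0.5, g09 = 0.25, g10 = 0.1)
  ranked <- demix:::.rankedGeneList(scores)
  members <- which(geneIds(ranked) %in% c("g01", "g03", "g07"))
  es <- demix:::.gseaES(abs(geneScores(ranked)), members, 1)
  expect_equal(es, naiveRunningSumES(geneScores(ranked), members))
  skip_if_not_installed("fgsea")
  expect_equal(es, fgsea::calcGseaStat(
    setNames(geneScores(ranked), geneIds(ranked)),
    selectedStats = members, gseaParam = 1))
})

test_that("closed-form ES agrees with the naive scan across random sets", {
  set.seed(97)
  for (i in 1:25) {
    N <- sample(20:120, 1)
    s <- sort(abs(rnorm(N, sd = 2)), decreasing = TRUE)
    n <- sample(3:10, 1)
    members <- sort(sample.int(N, n))
    expect_equal(demix:::.gseaES(s, members, 1),
                 naiveRunningSumES(s, members), tolerance = 1e-12)
  }
})

test_that("a top-concentrated set maximizes the enrichment score", {
  set.seed(101)
  scores <- setNames(sort(rlnorm(60, 0, 1), decreasing = TRUE),
                     sprintf("g%02d", 1:60))
  ranked <- demix:::.rankedGeneList(scores)
  gsc <- GeneSetCollection(list(
    best = geneIds(ranked)[1:5],
    mid = geneIds(ranked)[28:32],
    worst = geneIds(ranked)[56:60]))
  res <- suppressMessages(
    gseaPreranked(ranked, gsc, nPerm = 200, seed = 1))
  es <- setNames(res$statistic, res$set)
  expect_gt(es[["best"]], 0)
  expect_gt(es[["best"]], es[["mid"]])
  expect_lt(es[["worst"]], 0)
  expect_true(all(res$p_adjusted >= res$p_value))
})

test_that("ORA matches the closed-form hypergeometric tail", {
  ranked <- demix:::.rankedGeneList(
    setNames(seq(100, 1), sprintf("x%03d", 1:100)))
  gsc <- GeneSetCollection(list(inside = geneIds(ranked)[1:5],
                                outside = geneIds(ranked)[81:85]))
  res <- oraEnrichment(ranked, gsc, topFraction = 0.20)
  pin <- res$p_value[res$set == "inside"]
  expect_equal(pin, choose(20, 5) / choose(100, 5), tolerance = 1e-12)
  expect_equal(res$p_value[res$set == "outside"], 1)
  expect_identical(res$statistic[res$set == "inside"], Inf)
})

test_that("ORA equals exhaustive enumeration on a 12-gene universe", {
  ranked <- demix:::.rankedGeneList(
    setNames(seq(12, 1), sprintf("u%02d", 1:12)))
  for (setSize in c(3, 4, 6)) {
    gsc <- GeneSetCollection(list(s = geneIds(ranked)[seq_len(setSize)]))
    for (frac in c(0.25, 0.5)) {
      res <- oraEnrichment(ranked, gsc, topFraction = frac)
      selSize <- ceiling(frac * 12)
      oracle <- enumerationTailP(12, setSize, selSize, res$overlap)
      expect_equal(res$p_value, oracle, tolerance = 1e-12)
    }
  }
})

test_that("BH adjustment reproduces the hand-applied step-up", {
  expect_equal(adjustBH(0.037), 0.037)
  expect_equal(adjustBH(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(103)
  p <- runif(50)
  expect_true(all(adjustBH(p) >= p))
  expect_error(adjustBH(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("interpretation dispatches per component and is deterministic", {
  sim <- simulateExpressionMixture(K = 2, nFeatures = 200, nSamples = 14,
                                   nMarkersPerComponent = 10, noiseSd = 0.05,
                                   seed = 107)
  fit <- nmfDeconvolve(sim$matrix, K = 2, seed = 107)
  gsc <- GeneSetCollection(c(markerSets(sim$truth),
                             list(decoy = sprintf("g%05d", 150:160))))
  e1 <- suppressMessages(interpretComponents(fit, gsc, nPerm = 200, seed = 3))
  e2 <- suppressMessages(interpretComponents(fit, gsc, nPerm = 200, seed = 3))
  expect_identical(e1, e2)
  # continuous profiles -> every component tested by GSEA
  expect_true(all(e1$method == "GSEA"))
  expect_true(all(c("component", "set", "method", "statistic", "overlap",
                    "p_value", "p_adjusted") %in% colnames(e1)))
})

test_that("methylation interpretation requires a CpG map and uses it", {
  sim <- simulateMethylationMixture(K = 2, nFeatures = 120, nSamples = 10,
                                    nAnchorCpgs = 6, noiseSd = 0.02,
                                    seed = 109)
  fit <- edecDeconvolve(sim$matrix, K = 2, seed = 109)
  gsc <- GeneSetCollection(markerSets(sim$truth), minSize = 2L)
  expect_error(interpretComponents(fit, gsc, cpgMap = NULL), "cpgMap")
  enr <- suppressMessages(
    interpretComponents(fit, gsc, cpgMap = sim$cpgMap, nPerm = 100,
                        seed = 1, minSize = 2L))
  expect_true(all(grepl("^gene", unlist(geneSets(gsc)))))
  expect_s3_class(enr, "data.frame")
  expect_true(all(enr$p_adjusted >= enr$p_value - 1e-12))
})
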