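# demix

Reference-free cell-type deconvolution and biological interpretation of
bulk omics matrices, for bioinformaticians and analysts who have bulk
gene-expression or DNA-methylation profiles of heterogeneous samples
(tumors, blood, tissue) and no reference signatures for the cell types
inside them.

## The problem and the model

A bulk profile is a mixture of cell-type-specific signals. demix models a
features × samples matrix **X** (expression counts/intensities, or
methylation β-values in [0, 1]) as

```
X = T A,    T : features × K   (cell-type profiles, T ≥ 0; T ∈ [0,1] for β-values)
            A : K × samples    (proportions: A ≥ 0, colSums(A) = 1)
```

and estimates **T** and **A** jointly, with only the number of components
K supplied by the user. Four engines cover the standard reference-free
approaches:

| engine | idea | data |
|---|---|---|
| `nmf` | alternating exact constrained least squares (simplex A, non-negative T), pseudoinverse profile refit with negative clamping | expression, methylation |
| `edec` | same alternation with T box-constrained to [0, 1] (`max_its = 2000`, `rss_diff_stop = 1e-10`, 5 restarts) | methylation |
| `ica` | FastICA sources over genes, 30 top-weight markers per component, weighted-mean sample scores projected on the simplex | expression, methylation |
| `cam_lite` | simplified convex-geometry vertex search: k-means on row-normalized features (5K clusters), exhaustive K-subset corner scoring | expression, methylation |

Around the engines: CSV I/O, RPM and median-of-ratios normalization,
log2 / pseudo-log transforms, coefficient-of-variation feature selection,
PCA-eigenvalue scree guidance with an automatic mixture-aware elbow
suggestion for K, and component interpretation by preranked GSEA or
hypergeometric over-representation analysis (ORA) against GMT gene-set
collections, with CpG→gene max-aggregation for methylation and
Benjamini–Hochberg correction. A seeded simulator generates synthetic
expression and β-value mixtures with planted markers so the whole pipeline
is testable offline. See the vignette
(`vignettes/deconvolution-methods.Rmd`) for the methods and design
choices.

## Worked example

```r
library(demix)

## a three-cell-type cohort: 1000 genes x 24 bulk samples, 5% noise
sim <- simulateExpressionMixture(K = 3, nFeatures = 1000, nSamples = 24,
                                 nMarkersPerComponent = 30, noiseSd = 0.05,
                                 seed = 42)

## how many components do the data support?
(sc <- scree(sim$matrix))
#> ScreeResult: 24 eigenvalues (center=TRUE, scale=FALSE)
#>   suggested K (elbow, advisory): 3
#>   top eigenvalues: 23940000, 12700000, 152500, 120300, 72030, 59480, 52290, 41460

## deconvolve
(fit <- nmfDeconvolve(sim$matrix, K = nComponents(sc), seed = 42))
#> DeconvolutionResult: engine 'nmf', K = 3 (expression)
#>   1000 features x 24 samples; 145 iteration(s); final RSS 1.86169e+07
#>   mean proportions: C1=0.355 C2=0.330 C3=0.315

## how close are the estimated proportions to the truth?
mm <- matchComponents(fit, proportions(sim$truth))
round(c(mae = mm$mae, mm$correlations), 4)
#>    mae
#> 0.0323 0.9993 0.9993 0.9996

## which gene sets label each component?
gsc <- GeneSetCollection(markerSets(sim$truth))
enr <- interpretComponents(fit, gsc, nPerm = 1000, seed = 42)
head(enr, 4)
#>   component set method statistic overlap     p_value p_adjusted
#> 1         1  C3   GSEA 0.9126512      30 0.000999001    0.00300
#> 4         2  C2   GSEA 0.8977942      30 0.001000000    0.00300
#> 7         3  C1   GSEA 0.9248137      30 0.001000000    0.00300
#> 2         1  C1   GSEA 0.5745536      30 0.259000000    0.58275
```

Reading the output: the scree elbow suggests K = 3; the fitted proportion
matrix matches the simulated truth with mean absolute error 0.032 and
per-component correlations ≥ 0.999 (component labels are arbitrary, hence
the matching step); and each estimated component's top-ranked genes are
significantly enriched (GSEA enrichment scores ≈ 0.9, adjusted p = 0.003)
for exactly one planted marker set — estimated component 1 is cell type
C3, and so on.

A command-line interface wrapping the same functions ships in
`inst/scripts/demix` (subcommands `simulate`, `preprocess`, `estimate-k`,
`deconvolve`, `interpret`, `run`); `runPipeline()` chains all stages from
a single YAML config and writes the preprocessed matrix, proportions,
profiles, per-component top genes, enrichment table and diagnostics as
CSV/JSON.

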