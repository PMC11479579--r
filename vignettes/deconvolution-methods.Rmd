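---
title: "Reference-free deconvolution of bulk omics: models, algorithms and design choices"
author: "demix maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-free deconvolution of bulk omics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(demix)
```

## The mixture model

A bulk molecular profile is a weighted average of the profiles of the cell
types present in the sample. demix models a features x samples matrix
`X` (gene-expression counts/intensities, or DNA-methylation beta-values)
as

    X  =  T A,        T: features x K,   A: K x samples,

where `T` holds the cell-type-specific profiles and each column of `A` is a
vector of cell-type proportions: entries are non-negative and sum to one
(the probability simplex). *Reference-free* (unsupervised) deconvolution
estimates both `T` and `A` jointly, with only `K` supplied by the user.
Beta-value profiles additionally satisfy `0 <= T <= 1`.

Two facts about this model drive most design choices below:

1. **Compositional rank.** Because `1'A = 1'`, centering `X` across samples
   removes exactly one mixture dimension: a K-component mixture has a
   centered signal rank of K − 1.
2. **Scale indeterminacy.** The zero-residual set is generally not a point:
   the estimated mixing simplex can be expanded slightly outside the data
   cloud (with `T` compensating) without changing the fit. The solution is
   pinned only where constraints become active — profiles hitting 0 (or 1
   for beta-values) and samples lying at simplex vertices.

## Engines

### Alternating constrained least squares (NMF engine)

`nmfDeconvolve()` alternates two exact constrained least-squares steps:
per-feature non-negative regression of `X` on `A` (profiles), and
per-sample simplex-constrained regression of `X` on `T` (proportions; the
sum-to-one constraint is enforced *inside* the minimization, so proportions
are valid at every iteration and the residual sum of squares is provably
non-increasing). After convergence the profiles are recomputed from the
Moore–Penrose pseudoinverse, `T = X ginv(A)`, and negative entries are
clamped to zero — the usual sharpening step once proportions are fixed.

Each constrained subproblem is solved exactly: one shared unconstrained (or
equality-constrained) linear solve for all features/samples, KKT
verification, and a quadratic-programming fallback (`quadprog`) for the
columns whose active set differs. Stopping: relative RSS change below `tol`
(default 1e-6) or `maxIter` (default 500).

**Initialization.** The first start is a deterministic convex-geometry
guess: each feature row of a non-negative mixture, scaled to sum one, is a
convex combination of the scaled rows of `A`, so the scaled rows populate a
simplex whose corners are the components. k-means centers of the scaled
rows (5K clusters), thinned by a farthest-point sweep, provide near-corner
estimates of `A`. Additional random-simplex restarts (`nStarts`, default 3)
replace the geometric solution only when they improve the RSS by more than
0.1% — within the flat identifiability region described above, final RSS
values of different starts tie at convergence-depth noise, while the
geometric start is systematically the vertex-consistent representative. In
our six-component benchmarks this raises the minimum per-component
correlation with the truth from ~0.91–0.95 to >0.99 without changing the
fit quality.

### Box-constrained factorization for beta-values (EDec-style engine)

`edecDeconvolve()` is the same alternation with the profile step solved
under `0 <= T <= 1` per CpG, which is the appropriate constraint set for
methylation proportions-of-molecules. Defaults follow the published
stage-1 settings of this algorithm family: `maxIts = 2000`,
`rssDiffStop = 1e-10` (absolute RSS change), 5 restarts, best final RSS
kept. The bimodality of real beta-values (most CpGs near 0 or 1) is what
identifies the solution here: profiles at the box boundary forbid the
contraction/expansion drift.

### Independent component analysis with marker scoring (ICA engine)

`icaDeconvolve()` runs FastICA (logcosh nonlinearity, symmetric
decorrelation, seeded random orthonormal start) on the row-centered matrix
to extract K statistically independent source vectors over features. Each
component is reoriented so its largest-magnitude weight is positive
(`reorientComponents()`, ties to the smallest row index), its top
`nMarkers = 30` positively weighted genes are taken as markers, and each
sample is scored by the weighted mean of its marker rows. ICA produces
abundance scores, not proportions; by default the score columns are
projected onto the simplex by dividing by the column sum (disable with
`rescale = FALSE` to obtain the raw scores). Note that for a K-component
simplex mixture the proportion rows are linearly dependent (they sum to
one), so ICA can resolve at most K − 1 mixture directions plus noise; it
is most informative on data with general (non-compositional) mixing, and
the package therefore treats its output as exploratory scores rather than
a recovery-grade estimate.

### Simplified convex-geometry search (CAM-style engine)

`camLiteDeconvolve()` implements the scatter-simplex geometry directly:
row-normalized features are clustered (k-means, `5K` clusters), every
K-subset of cluster centers is scored by how well the remaining centers are
expressed as convex combinations of the subset, and the minimal-residual
subset is taken as the corner set. Proportions are the corner rows
renormalized per sample; profiles follow by non-negative least squares.
The subset search is exhaustive, hence the `K <= 6` and `5K <= 60` limits.
The geometric view carries an inherent per-component scale indeterminacy:
corners recover the proportion *rows* only up to scale, resolved by
projecting columns onto the simplex — exact when per-component total
abundances are balanced across the cohort, approximate otherwise.

### Component matching for evaluation

`matchComponents()` finds the assignment of estimated to true components
maximizing summed Pearson correlation of proportion rows. With `K <= 8`
(the tool's regime is `K <= 6`) the optimum is found by exhaustive
permutation search, which is exactly the Hungarian-algorithm optimum
without the extra dependency.

## Choosing K: the scree guidance

`scree()` reports the ordinary PCA eigenvalue spectrum (centered
covariance PCA by default; both `center` and `scale` are exposed) — this
plot is the primary guidance. The *automatic* suggestion handles the two
artifacts that defeat a naive elbow on mixture data:

- on the raw positive matrix, the first uncentered eigenvalue is a
  magnitude ("size") axis whose drop ratio ties with the true elbow;
- on the centered matrix, compositional rank loss (fact 1 above) parks the
  elbow at K − 1.

The suggestion therefore works on the *composition scale*: sample columns
are divided by their sums, the drop-ratio elbow
`argmax_k (λ_k − λ_{k+1}) / (λ_{k+1} − λ_min + 1e-12)` (k up to
`min(maxK, S−1)`) is located on the centered spectrum of the normalized
matrix — empirically a very reliable signal/noise edge detector — and the
suggested K is that elbow plus one. Data whose composition is constant
across samples (e.g. one profile under varying depth) are detected
(normalized centered variance ≈ 0) and suggest K = 1. In the six-component
benchmark at the default noise level this rule identifies K = 6 in 50/50
seeds; it is still advisory, and the eigenvalue table is always reported.

## Preprocessing

- `normalizeRPM()`: per-sample scaling to one million total counts.
- `normalizeMedianOfRatios()`: size factors as the median, over features
  positive in all samples, of the ratios to the per-feature geometric mean
  (the classic RNA-seq size-factor definition; checked against DESeq2 in
  the tests). Even-length medians use the midpoint.
- `transformValues()`: `log2(x + 1)` (the pseudocount keeps zero counts
  defined) or the pseudo-log `asinh(x / (2σ)) / ln 2` with σ = 1 by
  default — zero at zero, smooth, asymptotically `log2`.
- `selectFeaturesByCV()`: keeps the features with the largest sd/mean
  across samples; zero-mean features have undefined CV and are never
  selected; ties keep the original row order. CV is computed on the
  normalized, untransformed scale (selection before transformation), and
  the CV ranking is invariant under global rescaling of the matrix.

## Interpretation of components

For each component the features are ranked by their column of `T`
(descending, ties broken lexicographically so rankings are deterministic).
For methylation, CpG scores are first aggregated to genes by the maximum —
a gene contributes strongly if at least one of its CpGs does; unmapped
CpGs are dropped and counted. For ICA results the weight columns are
reoriented first (idempotent).

**Dispatch.** Preranked GSEA needs enough distinct values to order genes
reliably: if the fraction of distinct scores is at least 30% (inclusive
boundary; threshold exposed) the component is tested by GSEA, otherwise by
over-representation analysis.

**GSEA.** The weighted Kolmogorov–Smirnov running sum: scanning the
ranking, the sum gains `|score|^p` (normalized over the set, `p = 1`) at
members and loses `1/(N − n)` at non-members; the enrichment score is the
maximum deviation from zero (computed in closed form from the member
positions; positive deviations win exact ties). The null is `nPerm`
(default 1000) random same-size gene sets; the p-value is one-sided on the
observed sign with the +1 correction,
`p = (1 + #{same-sign nulls at least as extreme}) / (1 + #{same-sign
nulls})`, the convention that makes null p-values uniform (verified by a
calibration test: the fraction of null sets with p < 0.05 stays in
[0.02, 0.09]).

**ORA.** The selection is the top `ceiling(0.20 N)` of the ranking
(fraction exposed; ceiling so small universes never select zero genes),
the universe is all genes in the user's matrix, and the p-value is the
exact hypergeometric upper tail `P(overlap >= observed)`; the statistic is
the sample odds ratio. The ORA p-values are checked against exhaustive
enumeration of all selections on a 12-gene universe.

**Multiple testing.** The figure-level "adjusted p" is Benjamini–Hochberg
(`stats::p.adjust`), applied within each method pool (all GSEA tests
together, all ORA tests together) per run. Gene sets are read from GMT
(name, description, members); sets with fewer than 3 genes after
intersection with the universe are skipped, mirroring the common
"at least three markers per cell type" floor.

## The mixture simulator

`simulateExpressionMixture()` emulates a designed mixture cohort of K
distinct cell types: per-gene log-normal baseline (meanlog 5, sdlog 1 — a
realistic spread of expression magnitudes and CVs), mild per-type
log-normal variation (sdlog 0.25), `nMarkersPerComponent` markers
up-weighted 8-fold in their component only, Dirichlet(1) proportions, and
multiplicative log-normal noise. `simulateMethylationMixture()` draws
profiles from Beta(0.3, 0.3) (the bimodal shape of real beta-values),
plants anchor CpGs (0.95 in their component, 0.05 elsewhere) aligned to
synthetic genes (3 CpGs per gene), mixes with Dirichlet proportions, adds
truncated Gaussian noise and clips to [0, 1].

Two options exist because exact-recovery benchmarks need identifiable
conditions (fact 2 above): `pureMarkers` makes markers strictly
component-exclusive, and `pureSamples` plants purified (vertex) samples —
the in-silico analogue of profiling the purified constituent cell types
alongside the reconstituted mixtures, as designed benchmark datasets do.
Without vertex coverage, proportions are recoverable only up to a small
simplex expansion regardless of algorithm, and the simulator's default
(all-Dirichlet cohorts) reflects that harder, more realistic regime.

What the simulator does **not** model: per-gene negative-binomial
dispersion of read counts, batch effects, probe biases, or correlated
cell-type abundances. Passing the package's tests therefore demonstrates
correctness of the algorithms under the stated generative model, not
performance guarantees on any particular real dataset.

## Numerical choices and degenerate inputs

- Constrained least squares: KKT tolerance 1e-9; Gram matrices get an
  escalating ridge only if numerically singular; quadprog objectives are
  rescaled by their largest Gram entry (same argmin, better conditioning).
- RSS traces are recorded once per outer iteration and are non-increasing
  within 1e-9 relative slack.
- Ties: reorientation breaks |weight| ties at the smallest row index;
  gene rankings break score ties lexicographically; the CAM subset search
  takes the first minimal-score subset in `combn` order; CV selection
  keeps original row order among ties. All deterministic.
- Degenerate inputs error early with the offending identifier: duplicate
  ids, non-numeric cells, beta-values outside [0, 1], all-zero sample
  columns (RPM, scree), no all-positive feature (median-of-ratios),
  constant matrices (scree), all-zero weight columns (reorientation),
  non-positive ICA score sums.
- Seeds: every stochastic routine takes an explicit seed, restores the
  caller's RNG state, and is bit-reproducible given (input, K, seed).

## Problem sizes used in the validation suite

The shipped tests and the acceptance script validate on simulations of
2000 features x 36 samples with K = 6 (the six-cell-type regime), 50-seed
scree replications, 20-seed interpretation replications, and smaller
noiseless exact-recovery fixtures (300 x 12, K in 2–3) — sizes chosen so
the full suite completes in a few minutes on one CPU while keeping every
statistical check well-powered.

## Known limitations

- Plain ALS-NMF without sparsity or volume regularization: near-flat
  solution regions on hard (vertex-poor) cohorts are resolved by the
  geometric initialization heuristic, not by an identifiability-guaranteed
  objective.
- The CAM-style engine is a deliberately simplified vertex search
  (exhaustive subset scoring), not the full convex-analysis pipeline; its
  per-component scale resolution assumes balanced total abundances.
- ICA on compositional data resolves at most K − 1 mixture directions
  (see above).
- GSEA uses gene-permutation nulls only (no phenotype permutation — there
  are no phenotypes in this setting).
- No batch correction, missing-value imputation, or probe-level QC.
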