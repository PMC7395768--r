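---
title: "Methods: integrative analysis of the epidermal UV response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative analysis of the epidermal UV response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photomics)
```

photomics analyses paired multi-omics profiles of human epidermis sampled at
a UV-irradiated site and a contralateral control site of the same subject:
a gene × sample expression matrix (TPM) and a CpG × sample methylation matrix
(Beta values), with per-subject minimal erythema dose (MED, mJ/cm²) as the
quantitative UV-sensitivity phenotype. This vignette documents the models,
the tunable parameters, the synthetic-cohort generator used for validation,
and the numerical and design choices behind each stage.

## Paired differential analysis

Both omics levels are tested with the same paired design. Methylation is
analysed on the M scale, `M = log2(Beta / (1 − Beta))`, because M values are
approximately homoscedastic across the (0, 1) Beta range and therefore better
behaved in linear statistics; expression is analysed as `log2(TPM + 1)`. For
each feature we form per-subject differences `d_s = x_irradiated,s −
x_control,s`, removing all subject-level baseline variation, and report

- effect: `mean(d)` (the log2 fold-change; on the methylation level this is
  ΔM, itself a difference of log2 odds),
- `t = mean(d) / (sd(d)/√n)` with a two-sided p from the t distribution with
  n − 1 degrees of freedom,
- a Benjamini–Hochberg q-value across all features of the matrix.

This is a deliberate simplification relative to count-based negative-binomial
models and moderated-t pipelines: it keeps exactly the two ingredients the
downstream stages consume — the paired design and BH-FDR control — while
staying fully transparent and testable against closed forms. Features whose
paired differences have zero variance are flagged `degenerate`; their p is 1
when the effect is 0 and otherwise computed with a standard-deviation floor
of 1e-12.

The hypomethylation summary reports, among CpGs with q < 0.05, the fraction
with negative ΔM, overall and stratified by CpG-island relation (OpenSea →
Shelf → Shore → Island). Strata with no significant CpGs report `NA`, never
0, so an empty stratum cannot be mistaken for "no hypomethylation".

## DEMG selection and methylation–expression coupling

A differentially expressed and methylated gene (DEMG) is a gene passing the
expression thresholds (q < 0.05, |log2FC| > 0.5) that carries at least three
linked CpGs passing the methylation thresholds (q < 0.05, |ΔM| > 0.2) in a
non-intergenic region class (TSS200, TSS1500, exon or enhancer). All five
thresholds are configurable through `demg_criteria()`; the defaults are the
conventional FDR and effect cut-offs for this kind of analysis.

Regional coupling is quantified by simple linear regression of log2
expression on the unweighted mean M value of a gene's CpGs of one region
class, pooling both conditions into a single regression (subject pairing is
*not* modelled here — a deliberate simplification that mirrors how such
correlation analyses are usually pooled; the paired structure inflates the
effective correlation slightly, which is why these records are descriptive
rather than inferential in the pipeline summary). Each gene × class
combination is one test; BH correction is applied once across the pooled set
of tests so that "significant associations" are a single corrected family.

Block concordance compares the mean ΔM of the significant CpGs inside
externally defined genomic intervals (for example regions reported as
hypomethylated in chronically sun-exposed skin) against the interval's
reference methylation change. Intervals are BED-style 0-based half-open;
manifest positions are 1-based, and a CpG at position p belongs to
`[start, end)` iff `start < p ≤ end` — both conventions are asserted in code
to avoid off-by-one drift. A block is "concordant" when the sign of its
recovered mean effect matches the sign of its reference delta; blocks with
no significant CpG are reported but excluded from the block-level Pearson
correlation. The sign-match-plus-correlation definition is this package's
operationalisation of block agreement; magnitude agreement is not required
because acute and chronic exposure differ mainly in magnitude.

## Gene-set enrichment

Sample-wise enrichment uses the combined z-score: each gene's log2 expression
is standardized across samples (sample standard deviation, n − 1), and a set
S scores `Σ_{g∈S} z_g,s / √|S|` in sample s, restricted to set members
present with nonzero variance. Under independence the score of a union of
disjoint sets is the √-size-weighted combination of the parts, which the
test suite checks as an algebraic identity. Differential enrichment applies
the identical paired contract as the feature-level stage to the set × sample
score matrix. No separate over-representation test is performed; the z-score
method is the single enrichment primitive.

## MED prediction

`cross_validated_lasso()` predicts per-subject MED from molecular features
of one level (expression: log2(TPM+1); methylation: M values) or their
concatenation (`expr_`/`meth_` prefixes). Design choices:

- **Subject-grouped folds.** Both samples of a subject share the subject's
  MED, so sample-level folds would leak the target between a subject's
  control and irradiated sample. Outer folds (default 10) and inner
  penalty-selection folds (default 5) are therefore grouped by subject.
- **Penalty path.** 100 log-spaced values from λ_max down to 1e-4·λ_max;
  the inner CV minimises mean squared error.
- **Standardization without peeking.** Feature means/SDs are recomputed
  inside each training split and applied to its test split. The full-data
  statistics recorded by `assemble_features()` are reused only by the final
  all-data fit that reports nonzero coefficients.
- **Metrics.** Median absolute error (mJ/cm²), Pearson r, and R² computed as
  1 − SSE/SST on the pooled out-of-fold predictions, plus the same metrics
  restricted to irradiated-only and control-only samples, so performance can
  be compared regardless of exposure status.

## Similarity network fusion and molecular phototypes

Subtyping uses only the irradiated samples. Features of each level are first
ranked by |Pearson r| against MED and reduced to the top 10% (ties broken by
feature id for determinism). Per level, features are z-scored across the
retained samples and a locally scaled Gaussian kernel is built on Euclidean
distances:

    ε_ij = (mean d(i, kNN(i)) + mean d(j, kNN(j)) + d(i,j)) / 3
    W(i,j) = exp(−d(i,j)² / (α · ε_ij))

with k = 10 neighbours and α = 0.5. Fusion runs t = 20 cross-diffusion
steps: each level's status matrix (off-diagonal mass row-normalised to 1/2,
diagonal 1/2) is propagated through its sparse kNN kernel against the mean
of the other levels, re-normalised and symmetrised every step, and the
levels are averaged at the end. The per-iteration symmetrisation and the
1/2-mass normalisation variant are fixed here explicitly for
reproducibility. k, t, α and the prefilter fraction are all exposed through
`fusion_params()`.

Cluster count is estimated by the eigen-gap statistic on the symmetric
normalised Laplacian `L = I − D^{−1/2} W D^{−1/2}`: the K in [2, 5]
maximising `λ_{K+1} − λ_K` (ascending eigenvalues), smallest K on ties; a
rotation-cost criterion is not implemented. Spectral clustering embeds the
samples in the eigenvectors of the K smallest eigenvalues, row-normalises,
and runs k-means with 50 restarts under a fixed seed; labels are
canonicalised by first occurrence. Zero-degree (isolated) samples are a hard
error naming the sample.

## Pathway predictivity

Every gene set is scored by how well an SVM with radial-basis kernel
(γ = 1 / number of set genes present in the matrix, C = 1) discriminates
irradiated from control samples using only that set's expression, with
5×5-fold repeated stratified cross-validation and within-training-fold
standardization. γ uses the *present* gene count, not the nominal set size,
because that is the dimension of the feature space actually used. The map
stratifies scoring by molecular phototype (each subtype's subjects, both
conditions) and emits the unscaled accuracy matrix, unscaled row means, and
a per-row min–max scaled display matrix (rows with zero range map to 0.5).

Folds are stratified at the sample level, so the two samples of one subject
can fall into different folds. With paired data this is *conservative* for
uninformative sets: a held-out sample's nearest training neighbour is often
its own twin carrying the opposite label, which pushes null-set accuracies
below 0.5 rather than above. The synthetic tests quantify this: permuted
labels (which break the twin alignment) centre on 0.5, while null sets under
true labels score below chance. Informative sets are unaffected because the
condition signal dominates the twin similarity.

## The synthetic cohort generator

`generate_cohort()` + `generate_annotations()` produce, from one
configuration and seed, a fully paired cohort with a ground-truth ledger.
What it emulates — and its defaults, chosen once as the study conditions the
analysis assumes:

- **Design**: 32 subjects, two samples each; three latent subtypes in
  proportions 12/10/10 with MED ~ Normal(100/150/200, 15) mJ/cm² —
  increasing means spanning the range observed within a single Fitzpatrick
  phototype (roughly 100–210 mJ/cm²); the per-subtype distributions are not
  numerically calibrated to any published figure. Fitzpatrick labels are a
  noisy discretisation of MED, kept purely as cosmetic metadata emulating
  the known poor concordance between phototype and measured MED.
- **Methylation** is generated on the latent M scale (Gaussian baselines by
  island relation, bimodal as on arrays: islands unmethylated, open sea
  methylated), with subject effects (SD 0.5) and residual noise (SD 0.4),
  then mapped to Beta by the logistic transform — Beta is strictly inside
  (0, 1) by construction. 25% of CpGs receive an irradiation effect on the M
  scale with |ΔM| log-normal (median 0.5).
- **Hypomethylation bias**: among affected CpGs, exactly 65.1% (largest-
  remainder integer allocation) are negative, distributed over island
  relations with target hypo-fractions (0.58, 0.63, 0.69, 0.78) from open
  sea to island, rescaled so the overall fraction is exact. The recovered
  fraction among *significant* CpGs sits slightly below the planted value
  because BH false positives (sign-symmetric) dilute it — visible in the
  acceptance output and well inside the ±5 percentage-point band.
- **Expression**: Gaussian log2(TPM+1) baselines (uniform 2–8), subject
  effects (SD 0.8), noise (SD 0.5); 30% of genes shifted with |log2FC|
  log-normal (median 0.8); values floored at 0 before mapping back to TPM.
- **DEMG coupling**: 30% of affected genes are planted DEMGs. Their 4–6
  qualifying CpGs are drawn from the already-signed affected CpGs with a
  common sign and |ΔM| > 0.45, and the gene's log2FC sign is set opposite,
  with magnitude ≥ 0.7 — "most reliably changed" genes by construction. The
  re-use of already-signed CpGs keeps the global hypomethylation ledger
  exact.
- **MED-predictive features**: 20 genes and 20 CpGs per level with baselines
  linear in the subject's MED in both conditions (slope magnitude 0.8–1.2
  per 50 mJ/cm²), emulating constitutive markers of UV tolerance.
- **Subtype structure**: three response pathways of 40 genes each, shifted
  by ±1.5 (log2 / M units) only in the irradiated samples of their subtype,
  with 3 promoter/enhancer CpGs per gene carrying the same
  subtype-restricted shift. Both omics levels carry subtype signal because
  the subtypes are defined on the *fused* network. The magnitude was fixed
  at a level where the three subgroups are cleanly separated in the fused
  network — mirroring the well-separated subgroups the method is meant to
  detect — rather than at the detection boundary, where the eigen-gap
  statistic prefers a hierarchical 2-cluster reading of the same data.
- **Reference blocks**: 40 genomic windows (±15 CpGs around an anchor); 20
  are placed over coherent planted methylation change (≥3 affected members,
  |mean ΔM| ≥ 0.25) and record a same-sign reference delta amplified 2.5×
  (chronic exposure differs mainly in magnitude) plus small noise; the rest
  are placed at random with random reference deltas.
- **Gene sets**: the three subtype pathways, one shared UV-response set of
  40 upregulated affected genes, and 20 random null sets of 30 unaffected
  genes.

What it does **not** emulate: read-count sampling noise and library-size
effects, array batch and probe effects, cell-type composition shifts,
genomic autocorrelation of methylation beyond the planted blocks, and any
dose–response structure (dose is the binary condition label; the three
0.9-MED exposures are not modelled as a covariate). Passing recovery tests
on these cohorts therefore demonstrates that the statistical machinery is
correct and calibrated under the assumed generative structure — not that the
pipeline is robust to technical artefacts of real sequencing or array data.

## Problem sizes used in the tests

The validation suite runs the full default cohort (32 subjects, 2,000 genes,
20,000 CpGs) wherever a recovery claim depends on the study conditions:
subtype recovery over 20 generator seeds, the hypomethylation fraction over
10 seeds, MED models on all three feature levels, DEMG/block/pathway
recovery. Oracle and calibration checks (BH step-up on 1,000 random vectors,
OLS limit of the lasso at n = 20/p = 5, 500 global-null simulations of the
paired test at 200 features × 16 subjects, 100 label permutations of the
pathway score) use small fixtures where the closed form or the null is
exact. Unit tests of single operations use hand-computable fixtures of a few
features and samples.

## Known limitations

- The paired t on transformed values is not a count model; very low
  expression and extreme Beta values are handled by the +1 / clamp-and-M
  transforms rather than by a variance model.
- Correlation records pool paired samples without modelling the pairing.
- The eigen-gap is the only cluster-number criterion; rotation cost is not
  implemented.
- Sample-level CV in pathway scoring is conservative under pairing (see
  above); subject-grouped folds would remove the twin effect but are not
  what the predictivity map specifies.
- MED units are mJ/cm² throughout; no unit conversion is attempted on load.
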