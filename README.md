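# photomics

Integrative analysis of paired DNA methylation and transcriptome profiles of
UV-irradiated human epidermis.

## The problem

Acute solar UV exposure reprograms both the epidermal transcriptome and the
methylome, and individuals differ widely in their UV sensitivity — usually
summarised by the minimal erythema dose (MED, mJ/cm²), the smallest dose
producing skin redness. `photomics` implements the computational core of a
paired multi-omics study design: each subject contributes one sample from an
irradiated skin site and one from a contralateral control site, profiled for
gene expression (TPM) and CpG methylation (Beta values). The package is
aimed at computational biologists who want a tested, fully reproducible
pipeline for this design, together with a synthetic-cohort generator that
plants known effects so every stage can be validated by parameter recovery.

## What it computes

- **Paired differential analysis** — per-feature paired t statistics on
  `log2(TPM+1)` (expression) and M values `M = log2(β/(1−β))`
  (methylation), with Benjamini–Hochberg FDR; hypomethylation summaries
  stratified by CpG-island relation.
- **Methylation–expression integration** — DEMG selection (differentially
  expressed genes with ≥ 3 differentially methylated CpGs; thresholds
  FDR < 0.05, |log2FC| > 0.5, |ΔM| > 0.2), regional methylation
  aggregation, expression~methylation linear models with joint BH
  correction, and concordance with reference genomic blocks.
- **Gene-set enrichment** — sample-wise combined z-scores
  `Σ z_g / √|S|` with paired differential enrichment.
- **MED prediction** — subject-grouped 10-fold cross-validated lasso on
  expression, methylation, or combined features; median absolute error,
  Pearson r and R².
- **Molecular phototyping** — MED-correlation prefilter (top 10%),
  per-level locally scaled affinity kernels
  `W(i,j) = exp(−d²/(α·ε_ij))` (k = 10, α = 0.5), similarity network
  fusion (t = 20 cross-diffusion steps), eigen-gap selection of the cluster
  number, and spectral clustering into molecular phototypes.
- **Pathway predictivity** — per gene set, a radial-kernel SVM
  (γ = 1/|set|, C = 1) classifying irradiation status under 5×5-fold
  repeated CV, stratified by molecular phototype.
- **Synthetic cohorts** — `generate_cohort()` plants hypomethylation-biased
  irradiation effects (65.1% hypo, graded from open sea to CpG islands),
  coupled DEMGs, MED-linear features and three latent subtypes, with a full
  ground-truth ledger.

All result tables are tibbles; fitted objects support `tidy()`, `glance()`
and `autoplot()`.

## Worked example

```r
library(photomics)

cfg  <- cohort_config(seed = 1)          # 32 subjects, 2000 genes, 20000 CpGs
cc   <- generate_cohort(cfg)
ann  <- generate_annotations(cfg)

diff <- differential_cohort(cc$cohort)
hypomethylation_summary(diff$methylation, ann$manifest)
#> # A tibble: 5 × 3
#>   island_relation n_significant fraction_hypo
#>   <chr>                   <int>         <dbl>
#> 1 OpenSea                  2263         0.576
#> 2 Shelf                     510         0.624
#> 3 Shore                    1211         0.670
#> 4 Island                    953         0.764
#> 5 overall                  4937         0.640
```

24.7% of CpGs respond significantly; 64% of those lose methylation, and the
hypomethylation tendency increases from open-sea CpGs to CpG islands — the
signature the generator plants and the differential stage recovers.

```r
select_demgs(diff$expression, diff$methylation, ann$manifest)
#> <photomics_demg>
#> # A tibble: 2 × 4
#>   direction n_genes n_demg fraction_demg
#>   <chr>       <int>  <int>         <dbl>
#> 1 down          256     75         0.293
#> 2 up            345    148         0.429

subtype_cohort(cc$cohort, seed = 11)     # fusion + eigen-gap + clustering
#> <photomics_subtyping> best_k = 3; cluster sizes: 10/12/10

med <- cross_validated_lasso(assemble_features(cc$cohort, "combined"), seed = 5)
glance(med)
#> # A tibble: 1 × 3
#>     mae pearson_r r_squared
#>   <dbl>     <dbl>     <dbl>
#> 1  6.12     0.988     0.972
```

The eigen-gap recovers the three planted molecular phototypes, and the
combined expression + methylation lasso predicts MED with a median absolute
error of ~6 mJ/cm² out of fold. `run_pipeline(pipeline_config(synthetic =
cfg))` executes every stage in order and writes TSV/JSON artifacts plus a
`summary.json`.

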