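#' Configuration for a synthetic paired UV multi-omics cohort
#'
#' Defines the statistical structure of a simulated cohort of subjects sampled
#' at a UV-irradiated and a contralateral control site (two samples per
#' subject). Defaults emulate the design of an acute repetitive-irradiation
#' study of the human epidermis: 32 subjects in three latent molecular
#' phototypes of increasing minimal erythema dose (MED), a genome-wide
#' irradiation response biased towards hypomethylation (65.1% of affected CpGs
#' losing methylation) with the hypomethylation tendency increasing from
#' open-sea CpGs to CpG islands, a subset of differentially expressed genes
#' whose expression change is anti-correlated with the methylation change of
#' their promoter/enhancer CpGs (DEMGs), molecular features linear in MED on
#' both omics levels, and subtype-specific response pathways expressed on both
#' the transcriptome and the methylome.
#'
#' @param n_subjects Number of subjects; each contributes one control and one
#'   irradiated sample.
#' @param n_genes,n_cpgs Number of genes / CpG probes simulated.
#' @param subtype_proportions Length-3 simplex vector of latent subtype
#'   (molecular phototype) proportions.
#' @param med_means Strictly increasing per-subtype mean MED (mJ/cm^2).
#' @param med_sd Within-subtype MED standard deviation (mJ/cm^2).
#' @param frac_cpgs_affected Fraction of CpGs with a planted irradiation
#'   effect.
#' @param frac_hypo_among_affected Fraction of affected CpGs whose planted
#'   methylation change is negative (hypomethylation).
#' @param frac_genes_affected Fraction of genes with a planted irradiation
#'   effect on expression.
#' @param frac_demg Fraction of affected genes with coupled methylation
#'   (planted DEMGs).
#' @param n_med_predictive_features Number of features per omics level whose
#'   baseline is linear in the subject's MED (present in both conditions).
#' @param island_gradient Named non-decreasing hypo-fraction targets for
#'   OpenSea, Shelf, Shore, Island CpGs. Rescaled internally so the overall
#'   hypo fraction among affected CpGs equals `frac_hypo_among_affected`
#'   exactly (up to integer rounding).
#' @param effect_size_params List with `expr_meanlog`, `expr_sdlog`,
#'   `meth_meanlog`, `meth_sdlog`: log-normal location/scale of planted
#'   |log2 fold-change| (expression, on log2(TPM+1)) and |delta M|
#'   (methylation, on the M scale).
#' @param noise_sd Named numeric `c(expression = , methylation = )`: residual
#'   standard deviation per level (log2(TPM+1) and M units respectively).
#' @param seed Integer seed; the generator is fully deterministic given the
#'   configuration.
#' @param subject_sd Named numeric: between-subject (baseline) standard
#'   deviation per level; cancels in the paired differential stage.
#' @param island_relation_probs Marginal distribution of island relations
#'   across the array (EPIC-like composition).
#' @param genes_per_subtype_pathway,subtype_effect Number of genes per planted
#'   subtype-specific response pathway and the magnitude of their shift (log2
#'   units for expression, M units for the linked CpGs) in the irradiated
#'   samples of the matching subtype only.
#' @param cpgs_per_subtype_gene Promoter/enhancer CpGs linked to each subtype
#'   pathway gene, carrying the same subtype-restricted shift on the M scale.
#' @param demg_cpg_range Integer range of qualifying CpGs planted per DEMG.
#' @param n_null_sets,null_set_size Random (null) gene sets in the generated
#'   collection.
#' @param shared_pathway_size Size of the planted subtype-shared UV response
#'   set (drawn from upregulated affected genes).
#' @param n_blocks,n_concordant_blocks Genomic reference blocks generated; the
#'   concordant subset is placed over planted methylation changes with a
#'   reference delta of matching sign.
#'
#' @return An object of class `photomics_config` (a validated list).
#' @seealso [generate_cohort()], [generate_annotations()]
#' @export
#' @examples
#' cfg <- cohort_config(n_subjects = 8, n_genes = 100, n_cpgs = 500, seed = 7)
#' cfg$n_subjects
cohort_config <- function(n_subjects = 32,
                          n_genes = 2000,
                          n_cpgs = 20000,
                          subtype_proportions = c(12, 10, 10) / 32,
                          med_means = c(100, 150, 200),
                          med_sd = 15,
                          frac_cpgs_affected = 0.25,
                          frac_hypo_among_affected = 0.651,
                          frac_genes_affected = 0.3,
                          frac_demg = 0.3,
                          n_med_predictive_features = 20,
                          island_gradient = c(OpenSea = 0.58, Shelf = 0.63,
                                              Shore = 0.69, Island = 0.78),
                          effect_size_params = list(expr_meanlog = log(0.8),
                                                    expr_sdlog = 0.4,
                                                    meth_meanlog = log(0.5),
                                                    meth_sdlog = 0.4),
                          noise_sd = c(expression = 0.5, methylation = 0.4),
                          seed = 1,
                          subject_sd = c(expression = 0.8, methylation = 0.5),
                          island_relation_probs = c(OpenSea = 0.45, Shelf = 0.10,
                                                    Shore = 0.25, Island = 0.20),
                          genes_per_subtype_pathway = 40,
                          subtype_effect = 1.5,
                          cpgs_per_subtype_gene = 3,
                          demg_cpg_range = c(4L, 6L),
                          n_null_sets = 20,
                          null_set_size = 30,
                          shared_pathway_size = 40,
                          n_blocks = 40,
                          n_concordant_blocks = 20) {
  cfg <- list(
    n_subjects = as.integer(n_subjects), n_genes = as.integer(n_genes),
    n_cpgs = as.integer(n_cpgs), subtype_proportions = subtype_proportions,
    med_means = med_means, med_sd = med_sd,
    frac_cpgs_affected = frac_cpgs_affected,
    frac_hypo_among_affected = frac_hypo_among_affected,
    frac_genes_affected = frac_genes_affected, frac_demg = frac_demg,
    n_med_predictive_features = as.integer(n_med_predictive_features),
    island_gradient = island_gradient,
    effect_size_params = effect_size_params, noise_sd = noise_sd,
    seed = as.integer(seed), subject_sd = subject_sd,
    island_relation_probs = island_relation_probs,
    genes_per_subtype_pathway = as.integer(genes_per_subtype_pathway),
    subtype_effect = subtype_effect,
    cpgs_per_subtype_gene = as.integer(cpgs_per_subtype_gene),
    demg_cpg_range = as.integer(demg_cpg_range),
    n_null_sets = as.integer(n_null_sets),
    null_set_size = as.integer(null_set_size),
    shared_pathway_size = as.integer(shared_pathway_size),
    n_blocks = as.integer(n_blocks),
    n_concordant_blocks = as.integer(n_concordant_blocks)
  )
  class(cfg) <- "photomics_config"
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  if (length(cfg$subtype_proportions) != 3 ||
      abs(sum(cfg$subtype_proportions) - 1) > 1e-8 ||
      any(cfg$subtype_proportions < 0)) {
    abort("`subtype_proportions` must be a length-3 simplex vector (non-negative, summing to 1).")
  }
  if (length(cfg$med_means) != 3 || any(diff(cfg$med_means) <= 0)) {
    abort("`med_means` must be strictly increasing (one mean per subtype).")
  }
  assert_fraction(cfg$frac_cpgs_affected, "frac_cpgs_affected")
  assert_fraction(cfg$frac_hypo_among_affected, "frac_hypo_among_affected")
  assert_fraction(cfg$frac_genes_affected, "frac_genes_affected")
  assert_fraction(cfg$frac_demg, "frac_demg")
  grad <- cfg$island_gradient[c("OpenSea", "Shelf", "Shore", "Island")]
  if (any(is.na(grad))) {
    abort("`island_gradient` must be named with OpenSea, Shelf, Shore, Island.")
  }
  assert_fraction(unname(grad), "island_gradient")
  if (any(diff(grad) < 0)) {
    abort("`island_gradient` must be non-decreasing from OpenSea to Island.")
  }
  if (cfg$n_subjects < 3) abort("`n_subjects` must be at least 3.")
  if (cfg$med_sd <= 0) abort("`med_sd` must be positive.")
  cfg
}

#' @export
print.photomics_config <- function(x, ...) {
  cat("<photomics_config>\n")
  cat(sprintf("  %d subjects (2 samples each), %d genes, %d CpGs\n",
              x$n_subjects, x$n_genes, x$n_cpgs))
  cat(sprintf("  subtype proportions: %s; MED means: %s mJ/cm^2\n",
              paste(signif(x$subtype_proportions, 3), collapse = "/"),
              paste(x$med_means, collapse = "/")))
  cat(sprintf("  affected: %.0f%% of CpGs (%.1f%% hypo), %.0f%% of genes (%.0f%% DEMG)\n",
              100 * x$frac_cpgs_affected, 100 * x$frac_hypo_among_affected,
              100 * x$frac_genes_affected, 100 * x$frac_demg))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
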