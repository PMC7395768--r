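#' Configuration for an end-to-end pipeline run
#'
#' Exactly one of `synthetic` (a [cohort_config()]) or `paths` (named list of
#' files for [load_dataset()] plus `manifest`, `gmt`, `bed`) must be given.
#'
#' @param synthetic Optional [cohort_config()] for a simulated run.
#' @param paths Optional named list of input paths: `expression`,
#'   `methylation`, `samples`, `subjects`, `manifest`, `gmt`, `bed`.
#' @param output_dir Directory for stage artifacts.
#' @param demg [demg_criteria()].
#' @param fusion [fusion_params()].
#' @param predictivity [predictivity_params()] (its seed is overridden by the
#'   pipeline seed derivation).
#' @param med_outer_folds,med_inner_folds Cross-validation folds for the MED
#'   models.
#' @param q_threshold Significance threshold used in the summaries.
#' @param seed Single pipeline seed; per-stage seeds are derived from it
#'   deterministically so stages can be rerun in isolation.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(synthetic = NULL, paths = NULL,
                            output_dir = tempfile("photomics_run_"),
                            demg = demg_criteria(),
                            fusion = fusion_params(),
                            predictivity = predictivity_params(),
                            med_outer_folds = 10, med_inner_folds = 5,
                            q_threshold = 0.05, seed = 1) {
  if (is.null(synthetic) == is.null(paths)) {
    abort("Provide exactly one of `synthetic` or `paths`.")
  }
  structure(list(synthetic = synthetic, paths = paths,
                 output_dir = output_dir, demg = demg, fusion = fusion,
                 predictivity = predictivity,
                 med_outer_folds = as.integer(med_outer_folds),
                 med_inner_folds = as.integer(med_inner_folds),
                 q_threshold = q_threshold, seed = as.integer(seed)),
            class = "pipeline_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

#' Run the full integrative UV-response pipeline
#'
#' Executes, in dependency order: data generation/loading, paired
#' differential expression and methylation, DEMG selection and
#' expression-methylation correlation, block concordance, z-score gene-set
#' enrichment with paired differential enrichment, MED lasso models for all
#' three feature levels, similarity-network-fusion subtyping, and per-subtype
#' pathway predictivity. Stage outputs are written as TSV/JSON under
#' `config$output_dir`.
#'
#' @param config A [pipeline_config()] object.
#' @return List of class `photomics_run` with `summary` (named list, also
#'   written as `summary.json`), `artifacts` (named file paths) and the main
#'   in-memory results.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must be a pipeline_config().")
  }
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  art <- list()

  data <- run_stage("data", {
    if (!is.null(config$synthetic)) {
      cc <- generate_cohort(config$synthetic)
      ann <- generate_annotations(config$synthetic)
      list(cohort = cc$cohort, truth = cc$truth, manifest = ann$manifest,
           gene_sets = ann$gene_sets, blocks = ann$blocks)
    } else {
      p <- config$paths
      cohort <- load_dataset(p)
      ann <- load_annotations(p$manifest, p$gmt, p$bed,
                              expressed_genes = rownames(cohort$expression))
      list(cohort = cohort, truth = NULL, manifest = ann$manifest,
           gene_sets = ann$gene_sets, blocks = ann$blocks)
    }
  })
  cohort <- data$cohort
  expr_log <- log2(cohort$expression + 1)
  meth_m <- beta_to_m(cohort$methylation_beta)

  diff <- run_stage("differential", differential_cohort(cohort))
  hypo <- run_stage("hypomethylation_summary",
                    hypomethylation_summary(diff$methylation, data$manifest,
                                            config$q_threshold))
  readr::write_tsv(diff$expression,
                   art$differential_expression <- file.path(config$output_dir, "differential_expression.tsv"),
                   progress = FALSE)
  readr::write_tsv(diff$methylation,
                   art$differential_methylation <- file.path(config$output_dir, "differential_methylation.tsv"),
                   progress = FALSE)
  readr::write_tsv(hypo,
                   art$hypomethylation <- file.path(config$output_dir, "hypomethylation_summary.tsv"),
                   progress = FALSE)

  demg <- run_stage("demg", select_demgs(diff$expression, diff$methylation,
                                         data$manifest, config$demg))
  corr <- run_stage("correlation",
                    correlate_expression_methylation(expr_log, meth_m,
                                                     data$manifest))
  blocks <- run_stage("block_concordance",
                      block_concordance(diff$methylation, data$manifest,
                                        data$blocks, config$q_threshold))
  readr::write_tsv(demg$genes, art$demg <- file.path(config$output_dir, "demg_table.tsv"), progress = FALSE)
  readr::write_tsv(corr, art$correlation <- file.path(config$output_dir, "correlation_records.tsv"), progress = FALSE)
  readr::write_tsv(blocks$blocks, art$blocks <- file.path(config$output_dir, "block_concordance.tsv"), progress = FALSE)

  enr <- run_stage("enrichment", {
    scores <- zscore_enrichment(expr_log, data$gene_sets)
    list(scores = scores,
         differential = differential_enrichment(scores, cohort$samples))
  })
  readr::write_tsv(enr$differential,
                   art$enrichment <- file.path(config$output_dir, "differential_enrichment.tsv"),
                   progress = FALSE)

  med <- run_stage("med_models", {
    predict_med(cohort, outer_folds = config$med_outer_folds,
                inner_folds = config$med_inner_folds,
                seed = derive_seed(config$seed, 5L))
  })
  med_pred <- bind_rows(lapply(names(med), function(l) {
    med[[l]]$predictions |> mutate(level = l)
  }))
  readr::write_tsv(med_pred, art$med_predictions <- file.path(config$output_dir, "med_predictions.tsv"), progress = FALSE)

  subtyping <- run_stage("subtyping", {
    subtype_cohort(cohort, config$fusion, seed = derive_seed(config$seed, 6L))
  })
  readr::write_tsv(subtyping$assignment,
                   art$subtypes <- file.path(config$output_dir, "subtype_assignment.tsv"),
                   progress = FALSE)
  write_matrix_tsv(unclass(subtyping$fused),
                   art$fused <- file.path(config$output_dir, "fused_network.tsv"),
                   "sample_id")

  pred_params <- config$predictivity
  pred_params$seed <- derive_seed(config$seed, 7L)
  pmap <- run_stage("predictivity", {
    predictivity_map(expr_log, cohort$samples, subtyping$assignment,
                     data$gene_sets, pred_params)
  })
  readr::write_tsv(tidy(pmap), art$predictivity <- file.path(config$output_dir, "predictivity_map.tsv"), progress = FALSE)

  overall_hypo <- hypo$fraction_hypo[hypo$island_relation == "overall"]
  demg_frac <- function(dir) {
    v <- demg$summary$fraction_demg[demg$summary$direction == dir]
    if (length(v)) v else NA_real_
  }
  top_sets <- apply(pmap$accuracy, 2, function(col) {
    rownames(pmap$accuracy)[which.max(col)]
  })
  summary <- list(
    n_subjects = nrow(cohort$subjects),
    overall_hypo_fraction = overall_hypo,
    n_significant_cpgs = sum(diff$methylation$q_value < config$q_threshold),
    n_significant_genes = sum(diff$expression$q_value < config$q_threshold),
    demg_fraction_up = demg_frac("up"),
    demg_fraction_down = demg_frac("down"),
    n_significant_correlations = sum(corr$q_value < config$q_threshold),
    block_concordance_r = blocks$pearson_r,
    n_concordant_blocks = blocks$n_concordant,
    med_metrics = lapply(med, function(m) {
      as.list(glance(m))
    }),
    best_k = subtyping$best_k,
    subtype_sizes = as.list(table(subtyping$assignment$subtype)),
    top_predictive_pathways = as.list(top_sets),
    seed = config$seed
  )
  jsonlite::write_json(summary,
                       art$summary <- file.path(config$output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  structure(list(summary = summary, artifacts = art, differential = diff,
                 hypomethylation = hypo, demg = demg, correlation = corr,
                 blocks = blocks, enrichment = enr, med = med,
                 subtyping = subtyping, predictivity = pmap,
                 truth = data$truth),
            class = "photomics_run")
}

#' @export
print.photomics_run <- function(x, ...) {
  cat("<photomics_run>\n")
  cat(sprintf("  hypo fraction: %.3f; significant CpGs: %d; genes: %d\n",
              x$summary$overall_hypo_fraction, x$summary$n_significant_cpgs,
              x$summary$n_significant_genes))
  cat(sprintf("  best_k: %d; subtype sizes: %s\n", x$summary$best_k,
              paste(unlist(x$summary$subtype_sizes), collapse = "/")))
  invisible(x)
}
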