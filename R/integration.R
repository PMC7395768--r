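#' Thresholds for DEMG selection
#'
#' A gene is a differentially expressed and methylated gene (DEMG) when it is
#' significantly differentially expressed (q < `expr_q`, |log2FC| >
#' `expr_abs_effect`) and carries at least `min_cpgs` linked CpGs that are
#' significantly differentially methylated (q < `cpg_q`, |delta M| >
#' `cpg_abs_effect`) in a non-intergenic region class.
#'
#' @param expr_q,expr_abs_effect Expression significance / effect thresholds.
#' @param cpg_q,cpg_abs_effect CpG significance / effect thresholds (M scale).
#' @param min_cpgs Minimum number of qualifying CpGs.
#' @return A `demg_criteria` list.
#' @export
demg_criteria <- function(expr_q = 0.05, expr_abs_effect = 0.5,
                          cpg_q = 0.05, cpg_abs_effect = 0.2, min_cpgs = 3L) {
  if (min_cpgs < 1) abort("`min_cpgs` must be >= 1.")
  if (any(c(expr_q, expr_abs_effect, cpg_q, cpg_abs_effect) < 0)) {
    abort("Thresholds must be non-negative.")
  }
  structure(list(expr_q = expr_q, expr_abs_effect = expr_abs_effect,
                 cpg_q = cpg_q, cpg_abs_effect = cpg_abs_effect,
                 min_cpgs = as.integer(min_cpgs)),
            class = "demg_criteria")
}

#' Select differentially expressed and methylated genes (DEMGs)
#'
#' Counts, for every differentially expressed gene, the linked CpGs passing
#' the methylation thresholds (manifest links of any region class except
#' Intergenic) and flags genes with at least `min_cpgs` of them. The summary
#' reports the DEMG fraction separately among up- and downregulated genes.
#'
#' @param expr_diff,meth_diff Differential tables (expression / methylation).
#' @param manifest CpG manifest with gene links.
#' @param criteria A [demg_criteria()] object.
#' @return List of class `photomics_demg` with `genes` (tibble: gene_id,
#'   direction, n_qualifying_cpgs, de (expression-significant), demg) and
#'   `summary` (tibble: direction, n_genes, n_demg, fraction_demg).
#' @export
select_demgs <- function(expr_diff, meth_diff, manifest,
                         criteria = demg_criteria()) {
  links <- manifest_links(manifest) |>
    filter(.data$region_class != "Intergenic")
  qual_cpgs <- meth_diff |>
    filter(.data$q_value < criteria$cpg_q,
           abs(.data$effect) > criteria$cpg_abs_effect)
  qual_counts <- links |>
    filter(.data$cpg_id %in% qual_cpgs$feature_id) |>
    dplyr::distinct(.data$cpg_id, .data$gene_id) |>
    dplyr::count(.data$gene_id, name = "n_qualifying_cpgs")

  genes <- expr_diff |>
    select(gene_id = "feature_id", "effect", "q_value") |>
    left_join(qual_counts, by = "gene_id") |>
    mutate(
      n_qualifying_cpgs = dplyr::coalesce(.data$n_qualifying_cpgs, 0L),
      direction = ifelse(.data$effect >= 0, "up", "down"),
      de = .data$q_value < criteria$expr_q &
        abs(.data$effect) > criteria$expr_abs_effect,
      demg = .data$de & .data$n_qualifying_cpgs >= criteria$min_cpgs
    )
  absent <- setdiff(genes$gene_id, unique(manifest_links(manifest)$gene_id))
  if (length(absent)) {
    warn(sprintf("%d gene(s) in the differential table have no manifest CpG links (counted with 0 CpGs).",
                 length(absent)))
  }
  summary <- genes |>
    filter(.data$de) |>
    group_by(.data$direction) |>
    summarise(n_genes = n(), n_demg = sum(.data$demg),
              fraction_demg = mean(.data$demg), .groups = "drop")
  structure(list(genes = select(genes, "gene_id", "direction",
                                "n_qualifying_cpgs", "de", "demg"),
                 summary = summary, criteria = criteria),
            class = "photomics_demg")
}

#' @export
print.photomics_demg <- function(x, ...) {
  cat("<photomics_demg>\n")
  print(x$summary)
  invisible(x)
}

#' Aggregate methylation per gene within one functional region class
#'
#' For every gene with at least one linked CpG of the requested class, the
#' unweighted mean M value of those CpGs, per sample. A CpG linked to two
#' genes contributes to both rows.
#'
#' @param meth_m CpG x sample matrix of M values.
#' @param manifest CpG manifest with gene links.
#' @param region_class One of TSS200, TSS1500, Exon, Enhancer, Intergenic.
#' @return Gene x sample matrix of mean M values (possibly 0 rows).
#' @export
aggregate_regional_methylation <- function(meth_m, manifest, region_class) {
  if (!region_class %in% REGION_CLASSES) {
    abort(sprintf("Unknown region class '%s'.", region_class))
  }
  links <- manifest_links(manifest) |>
    filter(.data$region_class == !!region_class,
           .data$cpg_id %in% rownames(meth_m)) |>
    dplyr::distinct(.data$cpg_id, .data$gene_id)
  if (nrow(links) == 0) {
    warn(sprintf("No CpGs of class %s linked to any gene.", region_class))
    out <- matrix(numeric(0), nrow = 0, ncol = ncol(meth_m),
                  dimnames = list(character(0), colnames(meth_m)))
    return(out)
  }
  genes <- sort(unique(links$gene_id))
  out <- matrix(NA_real_, length(genes), ncol(meth_m),
                dimnames = list(genes, colnames(meth_m)))
  split_cpgs <- split(links$cpg_id, links$gene_id)
  for (g in genes) {
    rows <- split_cpgs[[g]]
    out[g, ] <- colMeans(meth_m[rows, , drop = FALSE])
  }
  out
}

#' Correlate gene expression with regional mean methylation
#'
#' For every gene x region class with data, a simple linear regression of
#' log2 expression on the mean M value of the linked CpGs of that class,
#' across all samples of both conditions pooled. Reports slope, Pearson r and
#' the slope p-value (t-test with n - 2 df), with a single
#' Benjamini-Hochberg correction pooled over all gene x class tests. Pairs
#' where either variable has zero variance are skipped (counted in the
#' `n_skipped` attribute).
#'
#' @param expr_log Gene x sample matrix of log2(TPM+1).
#' @param meth_m CpG x sample matrix of M values (same samples).
#' @param manifest CpG manifest with gene links.
#' @param classes Region classes to test.
#' @return Tibble of class `photomics_correlation`: gene_id, region_class,
#'   n_cpgs, pearson_r, slope, p_value, q_value.
#' @export
correlate_expression_methylation <- function(expr_log, meth_m, manifest,
                                             classes = c("Enhancer", "TSS1500",
                                                         "TSS200", "Exon")) {
  if (ncol(expr_log) < 4) abort("At least 4 shared samples are required.")
  links_all <- manifest_links(manifest)
  n_skipped <- 0L
  recs <- list()
  for (cl in classes) {
    regional <- aggregate_regional_methylation(meth_m, manifest, cl)
    genes <- intersect(rownames(regional), rownames(expr_log))
    if (!length(genes)) next
    n_cpg <- links_all |>
      filter(.data$region_class == cl, .data$gene_id %in% genes) |>
      dplyr::distinct(.data$cpg_id, .data$gene_id) |>
      dplyr::count(.data$gene_id)
    n_cpg_v <- setNames(n_cpg$n, n_cpg$gene_id)
    x <- regional[genes, colnames(expr_log), drop = FALSE]
    y <- expr_log[genes, , drop = FALSE]
    n <- ncol(y)
    vx <- apply(x, 1, sd); vy <- apply(y, 1, sd)
    ok <- vx > 0 & vy > 0
    n_skipped <- n_skipped + sum(!ok)
    if (!any(ok)) next
    x <- x[ok, , drop = FALSE]; y <- y[ok, , drop = FALSE]
    mx <- rowMeans(x); my <- rowMeans(y)
    sxx <- rowSums((x - mx)^2)
    sxy <- rowSums((x - mx) * (y - my))
    syy <- rowSums((y - my)^2)
    slope <- sxy / sxx
    r <- sxy / sqrt(sxx * syy)
    r <- pmin(pmax(r, -1), 1)
    se <- sqrt(pmax(syy - slope * sxy, 0) / (n - 2)) / sqrt(sxx)
    tval <- slope / pmax(se, 1e-300)
    p <- 2 * pt(abs(tval), df = n - 2, lower.tail = FALSE)
    recs[[cl]] <- tibble(
      gene_id = rownames(x), region_class = cl,
      n_cpgs = as.integer(n_cpg_v[rownames(x)]),
      pearson_r = unname(r), slope = unname(slope), p_value = unname(p)
    )
  }
  out <- bind_rows(recs)
  if (nrow(out)) out$q_value <- bh_adjust(out$p_value)
  attr(out, "n_skipped") <- n_skipped
  class(out) <- c("photomics_correlation", class(out))
  out
}

#' Concordance of methylation changes with reference genomic blocks
#'
#' For each reference block, the mean differential-methylation effect of its
#' significant member CpGs and whether its sign matches the block's reference
#' delta; plus the Pearson correlation between block mean effects and
#' reference deltas over blocks with at least one significant CpG.
#'
#' @param meth_diff Methylation differential table.
#' @param manifest CpG manifest (coordinates).
#' @param blocks Block tibble (block_id, chromosome, start, end,
#'   reference_delta).
#' @param q_threshold Significance threshold on q.
#' @return List of class `photomics_blocks` with `blocks` (per-block tibble:
#'   block_id, n_sig_cpgs, mean_effect, reference_delta, sign_match),
#'   `pearson_r` and `n_concordant`.
#' @export
block_concordance <- function(meth_diff, manifest, blocks, q_threshold = 0.05) {
  if (nrow(blocks) == 0) abort("Block table is empty.")
  off_chrom <- !blocks$chromosome %in% unique(manifest$chromosome)
  if (any(off_chrom)) {
    warn(sprintf("%d block(s) on chromosomes absent from the manifest; excluded.",
                 sum(off_chrom)))
    blocks <- blocks[!off_chrom, , drop = FALSE]
  }
  membership <- cpgs_in_blocks(manifest, blocks)
  sig <- meth_diff |> filter(.data$q_value < q_threshold)
  per_block <- membership |>
    filter(.data$cpg_id %in% sig$feature_id) |>
    left_join(sig |> select(cpg_id = "feature_id", "effect"), by = "cpg_id") |>
    group_by(.data$block_id) |>
    summarise(n_sig_cpgs = n(), mean_effect = mean(.data$effect),
              .groups = "drop")
  out <- blocks |>
    left_join(per_block, by = "block_id") |>
    mutate(n_sig_cpgs = dplyr::coalesce(.data$n_sig_cpgs, 0L),
           sign_match = .data$n_sig_cpgs > 0 &
             sign(.data$mean_effect) == sign(.data$reference_delta))
  with_data <- out |> filter(.data$n_sig_cpgs > 0)
  r <- if (nrow(with_data) >= 3 && sd(with_data$mean_effect) > 0 &&
           sd(with_data$reference_delta) > 0) {
    cor(with_data$mean_effect, with_data$reference_delta)
  } else {
    NA_real_
  }
  structure(list(
    blocks = select(out, "block_id", "chromosome", "start", "end",
                    "n_sig_cpgs", "mean_effect", "reference_delta",
                    "sign_match"),
    pearson_r = r,
    n_concordant = sum(out$sign_match, na.rm = TRUE),
    n_evaluated = nrow(with_data)
  ), class = "photomics_blocks")
}

#' @export
print.photomics_blocks <- function(x, ...) {
  cat(sprintf("<photomics_blocks> %d blocks with signal, %d sign-concordant, r = %.3f\n",
              x$n_evaluated, x$n_concordant, x$pearson_r))
  invisible(x)
}
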