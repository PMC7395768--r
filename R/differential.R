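#' Convert Beta values to M values
#'
#' `M = log2(Beta / (1 - Beta))`, the log2-odds of methylation. M values are
#' approximately homoscedastic and are used for all methylation statistics in
#' this package.
#'
#' @param beta Numeric vector/matrix with values strictly inside (0, 1).
#' @return M values of the same shape.
#' @export
#' @examples
#' beta_to_m(0.8) # 2
beta_to_m <- function(beta) {
  if (any(beta <= 0 | beta >= 1)) {
    abort("Beta values must lie strictly inside (0, 1); clamp on load.")
  }
  log2(beta / (1 - beta))
}

#' Convert M values back to Beta values
#' @param m Numeric vector/matrix of M values.
#' @return Beta values in (0, 1).
#' @export
m_to_beta <- function(m) {
  2^m / (1 + 2^m)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: sorted ascending, `q_(i) = min_{j >= i}
#' p_(j) * m / j`, capped at 1, returned in input order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  p.adjust(p_values, method = "BH")
}

#' Paired differential analysis
#'
#' Per-feature paired t-test of irradiated minus control differences, the
#' design used for both the expression (log2(TPM+1)) and methylation (M value)
#' level. For feature f with per-subject differences d_s: effect = mean(d),
#' t = mean(d) / (sd(d)/sqrt(n)), two-sided p from the t distribution with
#' n - 1 df, and Benjamini-Hochberg q across all features of the matrix.
#' Features with zero variance of the differences are flagged `degenerate`;
#' their p is 1 when the effect is 0, otherwise computed with a guarded
#' standard-deviation floor of 1e-12.
#'
#' @param mat Feature x sample numeric matrix (log2(TPM+1) or M values).
#' @param samples Sample table (tibble with `sample_id`, `subject_id`,
#'   `condition` in \{control, irradiated\}) covering every column of `mat`.
#' @return A tibble of class `photomics_differential` with columns
#'   `feature_id`, `effect`, `t_statistic`, `p_value`, `q_value`,
#'   `degenerate`; the number of subjects is stored in the `n_subjects`
#'   attribute.
#' @export
paired_differential <- function(mat, samples) {
  samples <- samples |> filter(.data$sample_id %in% colnames(mat))
  chk <- samples |>
    group_by(.data$subject_id) |>
    summarise(n_ctrl = sum(.data$condition == "control"),
              n_irr = sum(.data$condition == "irradiated"), .groups = "drop")
  if (any(chk$n_ctrl != 1 | chk$n_irr != 1)) {
    abort("Every subject must have exactly one control and one irradiated sample.")
  }
  subjects <- sort(chk$subject_id)
  n <- length(subjects)
  if (n < 3) abort("Paired differential analysis needs at least 3 subjects.")

  ctrl_cols <- samples$sample_id[match(paste0(subjects, ".control"),
                                       paste0(samples$subject_id, ".", samples$condition))]
  irr_cols <- samples$sample_id[match(paste0(subjects, ".irradiated"),
                                      paste0(samples$subject_id, ".", samples$condition))]
  d <- mat[, irr_cols, drop = FALSE] - mat[, ctrl_cols, drop = FALSE]

  effect <- rowMeans(d)
  sd_d <- sqrt(pmax(rowSums((d - effect)^2) / (n - 1), 0))
  degenerate <- sd_d < 1e-12
  sd_guard <- pmax(sd_d, 1e-12)
  t_stat <- effect / (sd_guard / sqrt(n))
  p <- 2 * pt(abs(t_stat), df = n - 1, lower.tail = FALSE)
  p[degenerate & effect == 0] <- 1
  t_stat[degenerate & effect == 0] <- 0
  if (any(degenerate & effect != 0)) {
    warn(sprintf("%d feature(s) with zero-variance paired differences and nonzero effect; p from guarded denominator.",
                 sum(degenerate & effect != 0)))
  }
  out <- tibble(
    feature_id = rownames(mat),
    effect = unname(effect),
    t_statistic = unname(t_stat),
    p_value = unname(p),
    q_value = bh_adjust(unname(p)),
    degenerate = unname(degenerate)
  )
  attr(out, "n_subjects") <- n
  class(out) <- c("photomics_differential", class(out))
  out
}

#' Paired differential analysis of a cohort
#'
#' Runs [paired_differential()] on the expression level (log2(TPM+1)) and the
#' methylation level (M values) of a cohort.
#'
#' @param cohort A `photomics_cohort`.
#' @return List with `expression` and `methylation` differential tables.
#' @export
differential_cohort <- function(cohort) {
  list(
    expression = paired_differential(log2(cohort$expression + 1), cohort$samples),
    methylation = paired_differential(beta_to_m(cohort$methylation_beta),
                                      cohort$samples)
  )
}

#' Hypomethylation summary by island relation
#'
#' Among significant CpGs (q below threshold), the fraction with negative
#' methylation change (delta M < 0), overall and stratified by CpG-island
#' relation. An effect of exactly 0 counts as non-hypo. Strata (or an input)
#' with zero significant CpGs report `NA` fractions rather than 0.
#'
#' @param meth_diff Differential table from the methylation level.
#' @param manifest CpG manifest covering the significant CpGs.
#' @param q_threshold Significance threshold on the BH q-value.
#' @return Tibble with rows for OpenSea, Shelf, Shore, Island and "overall":
#'   `island_relation`, `n_significant`, `fraction_hypo`.
#' @export
hypomethylation_summary <- function(meth_diff, manifest, q_threshold = 0.05) {
  sig <- meth_diff |> filter(.data$q_value < q_threshold)
  missing <- setdiff(sig$feature_id, manifest$cpg_id)
  if (length(missing)) {
    abort(sprintf("Significant CpG(s) missing from manifest: %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  rel <- manifest$island_relation[match(sig$feature_id, manifest$cpg_id)]
  per <- tibble(island_relation = factor(rel, levels = c("OpenSea", "Shelf",
                                                         "Shore", "Island")),
                hypo = sig$effect < 0) |>
    group_by(.data$island_relation, .drop = FALSE) |>
    summarise(n_significant = n(),
              fraction_hypo = ifelse(n() > 0, mean(.data$hypo), NA_real_),
              .groups = "drop") |>
    mutate(island_relation = as.character(.data$island_relation))
  overall <- tibble(
    island_relation = "overall",
    n_significant = nrow(sig),
    fraction_hypo = if (nrow(sig) > 0) mean(sig$effect < 0) else NA_real_
  )
  bind_rows(per, overall)
}

#' @method tidy photomics_differential
#' @export
tidy.photomics_differential <- function(x, ...) {
  as_tibble(x)
}

#' @method glance photomics_differential
#' @export
glance.photomics_differential <- function(x, q_threshold = 0.05, ...) {
  tibble(
    n_features = nrow(x),
    n_subjects = attr(x, "n_subjects"),
    n_significant = sum(x$q_value < q_threshold),
    fraction_significant = mean(x$q_value < q_threshold),
    fraction_negative_among_significant =
      if (any(x$q_value < q_threshold)) {
        mean(x$effect[x$q_value < q_threshold] < 0)
      } else NA_real_
  )
}
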