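#' Sample-wise z-score gene-set enrichment
#'
#' Combined z-score enrichment: each gene's log2 expression is standardized
#' across samples (z_g,s = (x_g,s - mean_s) / sd_s, sample sd with n - 1
#' denominator); the score of set S in sample s is
#' `sum_{g in S} z_g,s / sqrt(|S|)`, restricted to set members present in the
#' matrix with nonzero variance. Sets with no usable member are omitted with
#' a warning.
#'
#' @param expr_log Gene x sample matrix of log2(TPM+1); at least 2 samples.
#' @param gene_sets Named list of character vectors.
#' @return Gene-set x sample matrix of combined z scores (class
#'   `photomics_enrichment`); the genes actually used per set are stored in
#'   the `genes_used` attribute.
#' @export
zscore_enrichment <- function(expr_log, gene_sets) {
  if (ncol(expr_log) < 2) abort("At least 2 samples are required.")
  sds <- apply(expr_log, 1, sd)
  usable <- rownames(expr_log)[sds > 0]
  n_zero_var <- sum(sds == 0)
  z <- (expr_log[usable, , drop = FALSE] - rowMeans(expr_log[usable, , drop = FALSE])) /
    sds[usable]
  members <- lapply(gene_sets, intersect, y = usable)
  dropped_gene_sets <- sum(vapply(gene_sets, function(g) {
    length(intersect(g, usable)) < length(intersect(g, rownames(expr_log)))
  }, logical(1)))
  if (n_zero_var > 0 && dropped_gene_sets > 0) {
    warn(sprintf("%d zero-variance gene(s) dropped from gene sets.", n_zero_var))
  }
  keep <- lengths(members) > 0
  if (any(!keep)) {
    warn(sprintf("%d gene set(s) without expressed genes omitted: %s",
                 sum(!keep), paste(names(gene_sets)[!keep], collapse = ", ")))
  }
  members <- members[keep]
  scores <- t(vapply(members, function(g) {
    colSums(z[g, , drop = FALSE]) / sqrt(length(g))
  }, numeric(ncol(expr_log))))
  dimnames(scores) <- list(names(members), colnames(expr_log))
  attr(scores, "genes_used") <- members
  class(scores) <- c("photomics_enrichment", class(scores))
  scores
}

#' Paired differential gene-set enrichment
#'
#' Applies the paired differential contract of [paired_differential()] to a
#' set x sample enrichment score matrix: per set, effect = mean paired
#' (irradiated - control) score difference, paired t, BH q.
#'
#' @param scores Enrichment matrix from [zscore_enrichment()].
#' @param samples Sample table with subject pairing.
#' @return A `photomics_differential` tibble with one row per gene set.
#' @export
differential_enrichment <- function(scores, samples) {
  paired_differential(unclass(scores), samples)
}

#' @method autoplot photomics_enrichment
#' @export
autoplot.photomics_enrichment <- function(object, ...) {
  df <- as_tibble(unclass(object), rownames = "gene_set") |>
    tidyr::pivot_longer(-"gene_set", names_to = "sample_id",
                        values_to = "score")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_id, y = .data$gene_set,
                                   fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B") +
    ggplot2::labs(x = NULL, y = NULL, fill = "z score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1,
                                                       vjust = 0.5))
}
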