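#' Parameters for pathway predictivity scoring
#'
#' Support-vector classifiers with a radial basis kernel, `gamma = 1 /`
#' (number of set genes present in the expression matrix), `C = 1`, scored by
#' repeated stratified cross-validation.
#'
#' @param folds Folds per repeat (default 5).
#' @param repeats Number of repeats (default 5).
#' @param cost SVM cost parameter (default 1).
#' @param seed Integer seed for the fold assignments.
#' @return A `predictivity_params` list.
#' @export
predictivity_params <- function(folds = 5, repeats = 5, cost = 1, seed = 1) {
  if (folds < 2) abort("`folds` must be >= 2.")
  if (repeats < 1) abort("`repeats` must be >= 1.")
  structure(list(folds = as.integer(folds), repeats = as.integer(repeats),
                 cost = cost, seed = as.integer(seed)),
            class = "predictivity_params")
}

# stratified fold assignment: labels balanced across folds
stratified_folds <- function(labels, n_folds) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep(seq_len(n_folds), length.out = length(idx))
  }
  fold
}

#' Score one gene set's ability to discriminate irradiation status
#'
#' Restricts the expression matrix to the set's genes, then scores a radial
#' basis SVM (`gamma = 1 / n_set_genes`, `C` from `params`) by repeated
#' stratified cross-validation; features are standardized within each
#' training fold. The score is the mean fraction of correctly classified
#' held-out samples over all folds and repeats.
#'
#' @param expr_log Gene x sample matrix of log2(TPM+1).
#' @param labels Condition per sample (two classes, e.g. control/irradiated).
#' @param gene_set Character vector of gene ids.
#' @param params A [predictivity_params()] object.
#' @return Accuracy in \[0, 1\], or `NA` (with a warning) when no set gene is
#'   present in the matrix.
#' @export
pathway_score <- function(expr_log, labels, gene_set,
                          params = predictivity_params()) {
  genes <- intersect(gene_set, rownames(expr_log))
  if (length(genes) == 0) {
    warn("Gene set has no genes in the expression matrix; score omitted.")
    return(NA_real_)
  }
  labels <- factor(labels)
  if (nlevels(labels) != 2 || any(table(labels) < 2)) {
    abort("Need two classes with at least 2 samples each.")
  }
  n_folds <- params$folds
  min_class <- min(table(labels))
  if (min_class < n_folds) {
    warn(sprintf("Smallest class has %d samples; folds reduced to %d.",
                 min_class, min_class))
    n_folds <- min_class
  }
  x <- t(expr_log[genes, , drop = FALSE])
  gamma <- 1 / length(genes)

  withr::with_seed(params$seed, {
    accs <- numeric(0)
    for (rep_i in seq_len(params$repeats)) {
      fold <- stratified_folds(labels, n_folds)
      for (f in seq_len(n_folds)) {
        train <- fold != f
        std <- standardize_columns(x[train, , drop = FALSE])
        xtr <- std$z[, std$nonzero, drop = FALSE]
        if (ncol(xtr) == 0) { # all features constant in this training split
          pred_class <- names(which.max(table(labels[train])))
          accs <- c(accs, mean(labels[!train] == pred_class))
          next
        }
        xte <- sweep(x[!train, , drop = FALSE], 2, std$center, "-")
        xte <- sweep(xte, 2, ifelse(std$nonzero, std$scale, 1), "/")
        xte <- xte[, std$nonzero, drop = FALSE]
        fit <- e1071::svm(xtr, labels[train], kernel = "radial",
                          gamma = gamma, cost = params$cost, scale = FALSE)
        pred <- predict(fit, xte)
        accs <- c(accs, mean(pred == labels[!train]))
      }
    }
    mean(accs)
  })
}

#' Map pathway predictivity across molecular phototypes
#'
#' Scores every gene set within every subtype: the samples (both conditions)
#' of the subjects assigned to a subtype are scored with [pathway_score()]
#' against irradiation status. Emits the unscaled accuracy matrix, per-set
#' row means (unscaled), and a per-row min-max scaled display matrix (rows
#' with zero range map to 0.5). Subtypes with fewer than 2 subjects are
#' omitted with a warning.
#'
#' @param expr_log Gene x sample matrix of log2(TPM+1) over all samples.
#' @param samples Sample table (sample_id, subject_id, condition).
#' @param subtype_assignment Tibble with `subject_id` and `subtype`.
#' @param gene_sets Named list of gene sets.
#' @param params A [predictivity_params()] object.
#' @return Object of class `photomics_predictivity`: `accuracy` (set x
#'   subtype matrix), `row_means`, `scaled`.
#' @export
predictivity_map <- function(expr_log, samples, subtype_assignment, gene_sets,
                             params = predictivity_params()) {
  counts <- subtype_assignment |>
    dplyr::distinct(.data$subject_id, .data$subtype) |>
    dplyr::count(.data$subtype)
  keep <- counts$subtype[counts$n >= 2]
  if (length(keep) < length(unique(subtype_assignment$subtype))) {
    warn("Subtype(s) with fewer than 2 subjects omitted from the map.")
  }
  keep <- sort(keep)
  acc <- matrix(NA_real_, length(gene_sets), length(keep),
                dimnames = list(names(gene_sets), paste0("MP", keep)))
  for (j in seq_along(keep)) {
    subj <- subtype_assignment$subject_id[subtype_assignment$subtype == keep[j]]
    cols <- samples |> filter(.data$subject_id %in% subj)
    sub_expr <- expr_log[, cols$sample_id, drop = FALSE]
    for (i in seq_along(gene_sets)) {
      acc[i, j] <- pathway_score(sub_expr, cols$condition, gene_sets[[i]],
                                 params)
    }
  }
  row_means <- rowMeans(acc)
  rng <- apply(acc, 1, function(r) diff(range(r)))
  scaled <- t(apply(acc, 1, function(r) {
    if (diff(range(r)) == 0) rep(0.5, length(r)) else
      (r - min(r)) / diff(range(r))
  }))
  dimnames(scaled) <- dimnames(acc)
  structure(list(accuracy = acc, row_means = row_means, scaled = scaled,
                 params = params),
            class = "photomics_predictivity")
}

#' @export
print.photomics_predictivity <- function(x, ...) {
  cat(sprintf("<photomics_predictivity> %d gene sets x %d subtypes; top set: %s (mean accuracy %.3f)\n",
              nrow(x$accuracy), ncol(x$accuracy),
              names(which.max(x$row_means)), max(x$row_means)))
  invisible(x)
}

#' @method tidy photomics_predictivity
#' @export
tidy.photomics_predictivity <- function(x, ...) {
  as_tibble(x$accuracy, rownames = "gene_set") |>
    tidyr::pivot_longer(-"gene_set", names_to = "subtype",
                        values_to = "accuracy") |>
    left_join(
      as_tibble(x$scaled, rownames = "gene_set") |>
        tidyr::pivot_longer(-"gene_set", names_to = "subtype",
                            values_to = "scaled"),
      by = c("gene_set", "subtype")
    )
}

#' @method autoplot photomics_predictivity
#' @export
autoplot.photomics_predictivity <- function(object, ...) {
  df <- tidy(object)
  means <- tibble(gene_set = names(object$row_means),
                  mean_accuracy = unname(object$row_means))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$subtype,
                                   y = stats::reorder(.data$gene_set,
                                                      .data$accuracy),
                                   fill = .data$scaled)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "scaled\npredictivity",
                  caption = sprintf("top mean predictivity: %s (%.2f)",
                                    means$gene_set[which.max(means$mean_accuracy)],
                                    max(means$mean_accuracy))) +
    ggplot2::theme_minimal()
}
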