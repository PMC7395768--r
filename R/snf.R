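#' Parameters for similarity network fusion
#'
#' @param k Neighborhood size for the local kernels (default 10).
#' @param t Number of cross-diffusion iterations (default 20).
#' @param alpha Kernel bandwidth hyperparameter (default 0.5).
#' @param prefilter_fraction Fraction of features kept by the MED-correlation
#'   prefilter (default 0.10).
#' @return A `fusion_params` list.
#' @export
fusion_params <- function(k = 10, t = 20, alpha = 0.5,
                          prefilter_fraction = 0.10) {
  if (t < 1) abort("`t` must be >= 1.")
  if (alpha <= 0) abort("`alpha` must be positive.")
  if (prefilter_fraction <= 0 || prefilter_fraction > 1) {
    abort("`prefilter_fraction` must lie in (0, 1].")
  }
  structure(list(k = as.integer(k), t = as.integer(t), alpha = alpha,
                 prefilter_fraction = prefilter_fraction),
            class = "fusion_params")
}

#' Prefilter features by correlation with MED
#'
#' Ranks features by absolute Pearson correlation with the MED of the
#' corresponding subjects (descending, ties broken by feature id) and keeps
#' the top `ceiling(fraction * n_features)`.
#'
#' @param mat Feature x sample matrix.
#' @param med MED value per sample column.
#' @param fraction Fraction of features to keep.
#' @return The reduced feature x sample matrix.
#' @export
prefilter_by_med_correlation <- function(mat, med, fraction) {
  if (length(med) != ncol(mat)) abort("`med` must have one value per sample.")
  keep_n <- ceiling(fraction * nrow(mat))
  if (keep_n < 1) abort("Prefilter would keep no features.")
  sds <- apply(mat, 1, sd)
  r <- rep(0, nrow(mat))
  ok <- sds > 0 & sd(med) > 0
  if (any(ok)) r[ok] <- abs(as.numeric(cor(t(mat[ok, , drop = FALSE]), med)))
  ord <- order(-r, rownames(mat))
  mat[sort(ord[seq_len(keep_n)]), , drop = FALSE]
}

#' Build a sample affinity matrix from one data level
#'
#' Features are standardized (z across samples); d is the Euclidean distance;
#' the locally scaled bandwidth is
#' `eps_ij = (mean d(i, kNN(i)) + mean d(j, kNN(j)) + d(i, j)) / 3` and
#' `W(i, j) = exp(-d(i, j)^2 / (alpha * eps_ij))`.
#'
#' @param data Sample x feature matrix.
#' @param params A [fusion_params()] object.
#' @return Symmetric sample x sample affinity matrix with unit diagonal.
#' @export
build_affinity <- function(data, params = fusion_params()) {
  n <- nrow(data)
  if (n < params$k + 1) abort("Need at least k + 1 samples.")
  std <- standardize_columns(data)
  z <- std$z[, std$nonzero, drop = FALSE]
  d <- as.matrix(stats::dist(z))
  # mean distance to the k nearest neighbors (self excluded)
  knn_mean <- apply(d, 1, function(row) {
    mean(sort(row[-which.min(row)])[seq_len(params$k)])
  })
  # the above removes one minimal entry (the self zero)
  eps <- (outer(knn_mean, knn_mean, "+") + d) / 3
  eps <- pmax(eps, 1e-12)
  w <- exp(-d^2 / (params$alpha * eps))
  w <- (w + t(w)) / 2
  dimnames(w) <- list(rownames(data), rownames(data))
  w
}

snf_full_kernel <- function(w) {
  p <- w
  diag(p) <- 0
  rs <- rowSums(p)
  rs[rs == 0] <- 1
  p <- p / (2 * rs)
  diag(p) <- 0.5
  p
}

snf_sparse_kernel <- function(w, k) {
  n <- nrow(w)
  s <- matrix(0, n, n, dimnames = dimnames(w))
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    nn <- others[order(-w[i, others])][seq_len(min(k, n - 1))]
    s[i, nn] <- w[i, nn]
  }
  rs <- rowSums(s)
  rs[rs == 0] <- 1
  s / rs
}

#' Fuse per-level affinity networks by cross-diffusion
#'
#' Iterative similarity network fusion: each level's status matrix (full
#' kernel: off-diagonal mass 1/2 row-normalized, diagonal 1/2) is diffused
#' through its sparse k-nearest-neighbor kernel against the average of the
#' other levels' status matrices, `P_v <- S_v %*% mean_{u != v}(P_u) %*%
#' t(S_v)`, with re-normalization and symmetrization each step; after `t`
#' iterations the levels are averaged and symmetrized.
#'
#' @param affinities List of >= 2 affinity matrices over the same samples in
#'   the same order.
#' @param params A [fusion_params()] object.
#' @return Fused sample x sample similarity matrix (class `photomics_fused`).
#' @export
snf_fuse <- function(affinities, params = fusion_params()) {
  if (length(affinities) < 2) abort("At least 2 affinity levels are required.")
  ids <- lapply(affinities, rownames)
  if (!all(vapply(ids[-1], identical, logical(1), ids[[1]]))) {
    abort("All affinity matrices must share the same sample ids in the same order.")
  }
  p_list <- lapply(affinities, snf_full_kernel)
  s_list <- lapply(affinities, snf_sparse_kernel, k = params$k)
  m <- length(p_list)
  for (iter in seq_len(params$t)) {
    p_new <- vector("list", m)
    for (v in seq_len(m)) {
      others <- Reduce(`+`, p_list[-v]) / (m - 1)
      pv <- s_list[[v]] %*% others %*% t(s_list[[v]])
      pv <- snf_full_kernel((pv + t(pv)) / 2)
      p_new[[v]] <- (pv + t(pv)) / 2
    }
    p_list <- p_new
  }
  fused <- Reduce(`+`, p_list) / m
  fused <- (fused + t(fused)) / 2
  dimnames(fused) <- dimnames(affinities[[1]])
  class(fused) <- c("photomics_fused", class(fused))
  fused
}

normalized_laplacian <- function(w) {
  w <- unclass(w)
  deg <- rowSums(w)
  zero <- deg <= 0
  if (any(zero)) {
    abort(sprintf("Isolated sample(s) with zero degree: %s",
                  paste(rownames(w)[zero], collapse = ", ")))
  }
  d_inv_sqrt <- 1 / sqrt(deg)
  l <- -w * outer(d_inv_sqrt, d_inv_sqrt)
  diag(l) <- diag(l) + 1
  (l + t(l)) / 2
}

#' Spectral clustering on a fused network
#'
#' Normalized-cut spectral clustering: eigenvectors of the `n_clusters`
#' smallest eigenvalues of the symmetric normalized Laplacian
#' `L = I - D^{-1/2} W D^{-1/2}`, row-normalized, then k-means with 50
#' restarts under a fixed seed. Labels are canonicalized by first occurrence
#' (the first sample is always in cluster 1).
#'
#' @param network Fused (or any symmetric non-negative) similarity matrix.
#' @param n_clusters Number of clusters, `2 <= n_clusters < n_samples`.
#' @param seed Seed for the k-means restarts.
#' @return Integer vector of cluster labels named by sample.
#' @export
spectral_cluster <- function(network, n_clusters, seed = 1) {
  n <- nrow(network)
  if (n_clusters < 2 || n_clusters >= n) {
    abort("`n_clusters` must satisfy 2 <= n_clusters < n_samples.")
  }
  l <- normalized_laplacian(network)
  eig <- eigen(l, symmetric = TRUE)
  # columns of smallest eigenvalues
  emb <- eig$vectors[, n - seq_len(n_clusters) + 1, drop = FALSE]
  norms <- sqrt(rowSums(emb^2))
  emb <- emb / pmax(norms, 1e-12)
  km <- withr::with_seed(seed, kmeans(emb, centers = n_clusters, nstart = 50,
                                      iter.max = 100))
  labels <- km$cluster
  # canonical order: relabel by first occurrence
  first <- unique(labels)
  labels <- match(labels, first)
  setNames(as.integer(labels), rownames(network))
}

#' Estimate the number of clusters by the eigen-gap statistic
#'
#' Computes the ascending eigenvalues of the normalized Laplacian and the
#' gaps `eigengap(K) = lambda_{K+1} - lambda_K` for K in `[k_min, k_max]`.
#' The best K maximizes the gap; ties go to the smallest K.
#'
#' @param network Similarity matrix.
#' @param k_min,k_max Range of candidate cluster numbers.
#' @return List with `best_k` and `eigengaps` (tibble: k, eigengap).
#' @export
estimate_cluster_number <- function(network, k_min = 2, k_max = 5) {
  n <- nrow(network)
  if (k_max >= n) abort("`k_max` must be smaller than the number of samples.")
  l <- normalized_laplacian(network)
  lambda <- sort(eigen(l, symmetric = TRUE, only.values = TRUE)$values)
  ks <- seq(k_min, k_max)
  gaps <- lambda[ks + 1] - lambda[ks]
  best <- ks[which.max(gaps)] # which.max returns the first (smallest K) on ties
  list(best_k = as.integer(best),
       eigengaps = tibble(k = as.integer(ks), eigengap = gaps))
}

#' Full molecular-phototype subtyping path
#'
#' MED-correlation prefilter on irradiated samples, per-level affinities,
#' fusion, eigen-gap cluster-number estimation and spectral clustering.
#' Only irradiated samples enter the fusion; expression enters as
#' log2(TPM+1) and methylation as M values.
#'
#' @param cohort A `photomics_cohort`.
#' @param params A [fusion_params()] object.
#' @param n_clusters Optional fixed number of clusters; defaults to the
#'   eigen-gap estimate.
#' @param k_min,k_max Candidate range for the eigen-gap estimate.
#' @param seed Seed for the k-means step.
#' @return List of class `photomics_subtyping`: `fused` network, `labels`
#'   (per subject), `best_k`, `eigengaps`, `assignment` tibble.
#' @export
subtype_cohort <- function(cohort, params = fusion_params(), n_clusters = NULL,
                           k_min = 2, k_max = 5, seed = 1) {
  irr <- cohort$samples |> filter(.data$condition == "irradiated")
  med <- cohort$subjects$med[match(irr$subject_id, cohort$subjects$subject_id)]
  expr <- log2(cohort$expression[, irr$sample_id, drop = FALSE] + 1)
  meth <- beta_to_m(cohort$methylation_beta[, irr$sample_id, drop = FALSE])
  expr_f <- prefilter_by_med_correlation(expr, med, params$prefilter_fraction)
  meth_f <- prefilter_by_med_correlation(meth, med, params$prefilter_fraction)
  affinities <- list(expression = build_affinity(t(expr_f), params),
                     methylation = build_affinity(t(meth_f), params))
  fused <- snf_fuse(affinities, params)
  est <- estimate_cluster_number(fused, k_min, k_max)
  k_use <- n_clusters %||% est$best_k
  labels <- spectral_cluster(fused, k_use, seed = seed)
  assignment <- tibble(sample_id = irr$sample_id,
                       subject_id = irr$subject_id,
                       subtype = unname(labels))
  structure(list(fused = fused, labels = labels, best_k = est$best_k,
                 eigengaps = est$eigengaps, assignment = assignment,
                 params = params),
            class = "photomics_subtyping")
}

#' @export
print.photomics_subtyping <- function(x, ...) {
  cat(sprintf("<photomics_subtyping> best_k = %d; cluster sizes: %s\n",
              x$best_k, paste(table(x$labels), collapse = "/")))
  invisible(x)
}

#' @method tidy photomics_subtyping
#' @export
tidy.photomics_subtyping <- function(x, ...) {
  x$assignment
}

#' @method glance photomics_subtyping
#' @export
glance.photomics_subtyping <- function(x, ...) {
  tibble(best_k = x$best_k, n_samples = nrow(x$assignment),
         max_eigengap = max(x$eigengaps$eigengap))
}

#' @method autoplot photomics_fused
#' @export
autoplot.photomics_fused <- function(object, ...) {
  df <- as_tibble(unclass(object), rownames = "sample_i") |>
    tidyr::pivot_longer(-"sample_i", names_to = "sample_j",
                        values_to = "similarity")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_i, y = .data$sample_j,
                                   fill = .data$similarity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "fused\nsimilarity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Adjusted Rand index between two labelings
#'
#' @param a,b Two cluster label vectors over the same items.
#' @return The adjusted Rand index (1 = identical partitions).
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n <- choose2(sum(tab))
  expected <- sum_a * sum_b / n
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
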