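#' Assemble a feature matrix for MED prediction
#'
#' Builds the sample x feature matrix for one omics level or their
#' combination: expression features are log2(TPM+1), methylation features are
#' M values, combined is their column concatenation with level-tagged feature
#' ids (`expr_` / `meth_` prefixes, so collisions are impossible by
#' construction). Columns are standardized with full-data statistics (stored
#' in attributes for reuse by a final fit); zero-variance features are
#' dropped with a warning. Both samples of a subject share the subject's MED
#' as target.
#'
#' @param cohort A `photomics_cohort`.
#' @param level One of "expression", "methylation", "combined".
#' @return List with `x` (sample x feature standardized matrix, with `center`
#'   and `scale` attributes), `med` (target vector, mJ/cm^2) and `samples`
#'   (tibble aligned to the rows of `x`).
#' @export
assemble_features <- function(cohort,
                              level = c("combined", "expression", "methylation")) {
  level <- match.arg(level)
  parts <- list()
  if (level %in% c("expression", "combined")) {
    xe <- t(log2(cohort$expression + 1))
    colnames(xe) <- paste0("expr_", colnames(xe))
    parts$expr <- xe
  }
  if (level %in% c("methylation", "combined")) {
    xm <- t(beta_to_m(cohort$methylation_beta))
    colnames(xm) <- paste0("meth_", colnames(xm))
    parts$meth <- xm
  }
  x <- do.call(cbind, parts)
  stopifnot(!anyDuplicated(colnames(x)))
  std <- standardize_columns(x)
  if (any(!std$nonzero)) {
    warn(sprintf("%d zero-variance feature(s) dropped.", sum(!std$nonzero)))
  }
  x <- std$z[, std$nonzero, drop = FALSE]
  attr(x, "center") <- std$center[std$nonzero]
  attr(x, "scale") <- std$scale[std$nonzero]
  samples <- cohort$samples[match(rownames(x), cohort$samples$sample_id), ]
  med <- cohort$subjects$med[match(samples$subject_id,
                                   cohort$subjects$subject_id)]
  list(x = x, med = med, samples = samples)
}

fit_metrics <- function(observed, predicted) {
  if (length(observed) == 0) {
    return(tibble(mae = NA_real_, pearson_r = NA_real_, r_squared = NA_real_))
  }
  mae <- median(abs(predicted - observed))
  r <- if (sd(observed) > 0 && sd(predicted) > 0) {
    cor(observed, predicted)
  } else NA_real_
  sst <- sum((observed - mean(observed))^2)
  r2 <- if (sst > 0) 1 - sum((observed - predicted)^2) / sst else NA_real_
  tibble(mae = mae, pearson_r = r, r_squared = r2)
}

# subject-grouped fold assignment: both samples of a subject share a fold
subject_folds <- function(subjects, n_folds, seed) {
  withr::with_seed(seed, {
    shuffled <- sample(subjects)
    setNames(rep(seq_len(n_folds), length.out = length(subjects)),
             shuffled)
  })
}

#' Cross-validated lasso prediction of MED
#'
#' L1-regularized linear prediction of the minimal erythema dose from
#' molecular features. Outer cross-validation folds are grouped by subject
#' (both samples of a subject fall in the same fold, preventing leakage
#' between a subject's control and irradiated sample); within each training
#' split the penalty is chosen by inner subject-grouped cross-validation
#' minimizing mean squared error over a log-spaced path of 100 values down to
#' 1e-4 of the largest penalty. Feature standardization is recomputed inside
#' each training fold and applied to its test fold. Out-of-fold predictions
#' are pooled; the median absolute error, Pearson r and R^2
#' (1 - SSE/SST) are reported pooled and per condition. A final model is fit
#' on all data with an inner-CV-selected penalty to report the nonzero
#' coefficients.
#'
#' @param features Result of [assemble_features()], or a compatible list with
#'   `x`, `med`, `samples`.
#' @param outer_folds Number of outer folds (default 10).
#' @param inner_folds Number of inner folds for penalty selection.
#' @param seed Integer seed controlling fold assignment.
#' @param lambda Optional fixed penalty that bypasses the inner CV (e.g. a
#'   very large value yields full shrinkage: every prediction equals the
#'   training-fold mean MED).
#' @return Object of class `photomics_med_report`: `predictions` (per-sample
#'   out-of-fold tibble), `metrics` (pooled / irradiated / control rows),
#'   `fold_lambda`, `coefficients` (nonzero features of the full-data fit).
#' @export
cross_validated_lasso <- function(features, outer_folds = 10, inner_folds = 5,
                                  seed = 1, lambda = NULL) {
  x <- features$x; y <- features$med; samples <- features$samples
  subjects <- unique(samples$subject_id)
  if (outer_folds > length(subjects)) {
    abort("More outer folds than subjects.")
  }
  if (nrow(x) < 2 * outer_folds) {
    abort("Need at least 2 samples per outer fold.")
  }
  fold_of <- subject_folds(subjects, outer_folds, seed)
  sample_fold <- fold_of[samples$subject_id]

  pred <- rep(NA_real_, nrow(x))
  fold_lambda <- rep(NA_real_, outer_folds)
  for (f in seq_len(outer_folds)) {
    test <- which(sample_fold == f)
    train <- which(sample_fold != f)
    fit <- lasso_fold_fit(x[train, , drop = FALSE], y[train],
                          samples$subject_id[train], inner_folds,
                          seed = derive_seed(seed, f), lambda = lambda)
    pred[test] <- lasso_fold_predict(fit, x[test, , drop = FALSE])
    fold_lambda[f] <- fit$lambda
  }

  predictions <- tibble(
    sample_id = samples$sample_id, subject_id = samples$subject_id,
    condition = samples$condition, observed = y, predicted = pred,
    fold = unname(sample_fold)
  )
  metrics <- bind_rows(
    fit_metrics(y, pred) |> mutate(subset = "pooled"),
    fit_metrics(y[samples$condition == "irradiated"],
                pred[samples$condition == "irradiated"]) |>
      mutate(subset = "irradiated"),
    fit_metrics(y[samples$condition == "control"],
                pred[samples$condition == "control"]) |>
      mutate(subset = "control")
  ) |> select("subset", "mae", "pearson_r", "r_squared")

  full <- lasso_fold_fit(x, y, samples$subject_id, inner_folds,
                         seed = derive_seed(seed, 0L), lambda = lambda)
  coefs <- lasso_nonzero_coefficients(full)

  structure(list(predictions = predictions, metrics = metrics,
                 fold_lambda = tibble(fold = seq_len(outer_folds),
                                      lambda = fold_lambda),
                 coefficients = coefs, level_features = colnames(x)),
            class = "photomics_med_report")
}

# fit one training split: per-fold standardization, subject-grouped inner CV
lasso_fold_fit <- function(x, y, subject_id, inner_folds, seed, lambda = NULL) {
  std <- standardize_columns(x)
  xs <- std$z[, std$nonzero, drop = FALSE]
  if (sd(y) == 0) {
    return(list(type = "constant", value = mean(y), std = std, lambda = NA_real_))
  }
  if (!is.null(lambda)) {
    fit <- glmnet::glmnet(xs, y, alpha = 1, standardize = FALSE,
                          thresh = 1e-12)
    return(list(type = "glmnet", fit = fit, std = std, lambda = lambda,
                exact = TRUE, xs = xs, y = y))
  }
  train_subjects <- unique(subject_id)
  k <- min(inner_folds, length(train_subjects))
  inner <- subject_folds(train_subjects, k, seed)
  foldid <- unname(inner[subject_id])
  cv <- glmnet::cv.glmnet(xs, y, alpha = 1, foldid = foldid,
                          nlambda = 100, lambda.min.ratio = 1e-4,
                          standardize = FALSE)
  list(type = "glmnet", fit = cv$glmnet.fit, std = std, lambda = cv$lambda.min)
}

lasso_fold_predict <- function(fit, newx) {
  if (fit$type == "constant") return(rep(fit$value, nrow(newx)))
  std <- fit$std
  z <- sweep(newx, 2, std$center, "-")
  z <- sweep(z, 2, ifelse(std$nonzero, std$scale, 1), "/")
  z <- z[, std$nonzero, drop = FALSE]
  if (isTRUE(fit$exact)) {
    # a user-fixed penalty may lie outside the fitted path; refit exactly
    return(as.numeric(predict(fit$fit, newx = z, s = fit$lambda,
                              exact = TRUE, x = fit$xs, y = fit$y)))
  }
  as.numeric(predict(fit$fit, newx = z, s = fit$lambda, exact = FALSE))
}

lasso_nonzero_coefficients <- function(fit) {
  if (fit$type == "constant") {
    return(tibble(feature = "(Intercept)", coefficient = fit$value))
  }
  cf <- if (isTRUE(fit$exact)) {
    as.matrix(coef(fit$fit, s = fit$lambda, exact = TRUE, x = fit$xs,
                   y = fit$y))
  } else {
    as.matrix(coef(fit$fit, s = fit$lambda, exact = FALSE))
  }
  nz <- which(abs(cf[, 1]) > 0)
  tibble(feature = rownames(cf)[nz], coefficient = unname(cf[nz, 1]))
}

#' Run MED prediction for one or more feature levels
#'
#' @param cohort A `photomics_cohort`.
#' @param levels Character vector of levels to fit.
#' @param ... Passed to [cross_validated_lasso()].
#' @return Named list of `photomics_med_report` objects.
#' @export
predict_med <- function(cohort, levels = c("expression", "methylation",
                                           "combined"), ...) {
  setNames(lapply(levels, function(l) {
    cross_validated_lasso(assemble_features(cohort, l), ...)
  }), levels)
}

#' @export
print.photomics_med_report <- function(x, ...) {
  cat("<photomics_med_report>\n")
  print(x$metrics)
  cat(sprintf("  %d nonzero coefficient(s) in the full-data fit\n",
              sum(x$coefficients$feature != "(Intercept)")))
  invisible(x)
}

#' @method tidy photomics_med_report
#' @export
tidy.photomics_med_report <- function(x, ...) {
  x$predictions
}

#' @method glance photomics_med_report
#' @export
glance.photomics_med_report <- function(x, ...) {
  x$metrics |> filter(.data$subset == "pooled") |> select(-"subset")
}

#' @method autoplot photomics_med_report
#' @export
autoplot.photomics_med_report <- function(object, ...) {
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(x = .data$observed, y = .data$predicted,
                               colour = .data$condition)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "observed MED (mJ/cm²)",
                  y = "cross-validated prediction (mJ/cm²)") +
    ggplot2::theme_minimal()
}
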