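test_that("feature assembly concatenates levels with prefixes and standardizes", {
  cc <- generate_cohort(tiny_config(seed = 13, n_genes = 100, n_cpgs = 500))
  f <- assemble_features(cc$cohort, "combined")
  expect_lte(ncol(f$x), 600)
  expect_gte(ncol(f$x), 590) # only zero-variance columns may drop
  expect_true(all(grepl("^(expr|meth)_", colnames(f$x))))
  expect_true(all(abs(colMeans(f$x)) < 1e-9))
  expect_true(all(abs(apply(f$x, 2, sd) - 1) < 1e-9))
  # both samples of a subject share the subject's MED
  med_by_subj <- tapply(f$med, f$samples$subject_id, function(v) diff(range(v)))
  expect_true(all(med_by_subj == 0))
})

test_that("the lasso at vanishing penalty matches an OLS oracle", {
  withr::with_seed(31, {
    n <- 20; p <- 5
    x <- matrix(rnorm(n * p), n, p,
                dimnames = list(paste0("s", 1:n), paste0("f", 1:p)))
    beta <- c(2, -1, 0.5, 0, 1)
    y <- drop(x %*% beta) + rnorm(n, 0, 0.01)
    feats <- list(x = x, med = y,
                  samples = tibble::tibble(sample_id = rownames(x),
                                           subject_id = rownames(x),
                                           condition = "irradiated"))
    rep <- cross_validated_lasso(feats, outer_folds = 4, inner_folds = 3,
                                 seed = 1, lambda = 1e-8)
    # the model fits standardized predictors; compare on that scale
    xs <- scale(x)
    ols <- coef(lm(y ~ xs))
    got <- setNames(rep$coefficients$coefficient, rep$coefficients$feature)
    expect_equal(unname(got[paste0("f", 1:p)]), unname(ols[-1]),
                 tolerance = 1e-4)
  })
})

test_that("degenerate penalties behave as contracts say", {
  withr::with_seed(32, {
    n_subj <- 12
    subj <- sprintf("P%02d", 1:n_subj)
    samples <- paired_samples(subj) |> dplyr::arrange(subject_id, condition)
    x <- matrix(rnorm(24 * 6), 24, 6,
                dimnames = list(samples$sample_id, paste0("f", 1:6)))
    # constant MED: predictions constant, MAE ~ 0, r undefined
    feats <- list(x = x, med = rep(150, 24), samples = samples)
    rep0 <- cross_validated_lasso(feats, outer_folds = 4, seed = 2)
    expect_equal(unique(round(rep0$predictions$predicted, 10)), 150)
    expect_equal(rep0$metrics$mae[rep0$metrics$subset == "pooled"], 0)
    expect_true(is.na(rep0$metrics$pearson_r[rep0$metrics$subset == "pooled"]))

    # infinite penalty: every prediction is the training-fold mean MED
    med <- rnorm(n_subj, 150, 30)[match(samples$subject_id, subj)]
    feats2 <- list(x = x, med = med, samples = samples)
    rep_inf <- cross_validated_lasso(feats2, outer_folds = 4, seed = 2,
                                     lambda = 1e10)
    for (f in unique(rep_inf$predictions$fold)) {
      in_f <- rep_inf$predictions$fold == f
      expect_equal(unique(round(rep_inf$predictions$predicted[in_f], 8)),
                   round(mean(med[!in_f]), 8))
    }
  })
})

test_that("folds are grouped by subject and fold count is validated", {
  cc <- generate_cohort(tiny_config(seed = 14))
  f <- suppressWarnings(assemble_features(cc$cohort, "expression"))
  rep <- cross_validated_lasso(f, outer_folds = 4, inner_folds = 3, seed = 3)
  per_subj <- tapply(rep$predictions$fold, rep$predictions$subject_id,
                     function(v) length(unique(v)))
  expect_true(all(per_subj == 1))
  expect_equal(sort(table(rep$predictions$sample_id)), sort(table(rep$predictions$sample_id)))
  expect_equal(nrow(rep$predictions), nrow(f$x))
  expect_error(cross_validated_lasso(f, outer_folds = 99), "folds")
})

test_that("a planted linear MED signal is recovered with high out-of-fold correlation", {
  withr::with_seed(33, {
    n_subj <- 30
    subj <- sprintf("P%02d", 1:n_subj)
    samples <- paired_samples(subj) |> dplyr::arrange(subject_id, condition)
    med_subj <- rnorm(n_subj, 150, 40)
    med <- med_subj[match(samples$subject_id, subj)]
    p_inf <- 5; p_noise <- 45
    slopes <- runif(p_inf, 0.8, 1.2) * sample(c(-1, 1), p_inf, replace = TRUE)
    x_inf <- outer((med - 150) / 50, slopes) + matrix(rnorm(60 * p_inf, 0, 0.2),
                                                      60, p_inf)
    x_noise <- matrix(rnorm(60 * p_noise), 60, p_noise)
    x <- cbind(x_inf, x_noise)
    dimnames(x) <- list(samples$sample_id,
                        c(paste0("inf", 1:p_inf), paste0("noise", 1:p_noise)))
    feats <- list(x = x, med = med, samples = samples)
    rep <- cross_validated_lasso(feats, outer_folds = 10, inner_folds = 5,
                                 seed = 4)
    expect_gte(rep$metrics$pearson_r[rep$metrics$subset == "pooled"], 0.9)
    nz <- rep$coefficients$feature
    planted_kept <- sum(paste0("inf", 1:p_inf) %in% nz)
    expect_gte(planted_kept, 4)
    # coefficient mass concentrates on the planted features
    w <- abs(rep$coefficients$coefficient[rep$coefficients$feature != "(Intercept)"])
    names(w) <- setdiff(rep$coefficients$feature, "(Intercept)")
    expect_gt(sum(w[grepl("^inf", names(w))]) / sum(w), 0.8)
  })
})
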