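test_that("MED-correlation prefilter ranks and tie-breaks as specified", {
  withr::with_seed(41, {
    med <- rnorm(20)
    m <- matrix(rnorm(200), 10, 20,
                dimnames = list(paste0("f", sprintf("%02d", 1:10)), NULL))
    expect_identical(prefilter_by_med_correlation(m, med, 1), m)
    top1 <- prefilter_by_med_correlation(m, med, 0.1)
    r <- abs(apply(m, 1, cor, y = med))
    expect_equal(rownames(top1), names(which.max(r)))
    empty <- m[integer(0), , drop = FALSE]
    expect_error(prefilter_by_med_correlation(empty, med, 0.5), "no features")

    # ties (zero-variance rows all have r set to 0) break lexicographically
    flat <- matrix(1, 4, 20, dimnames = list(c("b", "a", "d", "c"), NULL))
    kept <- prefilter_by_med_correlation(flat, med, 0.5)
    expect_setequal(rownames(kept), c("a", "b"))
  })
})

test_that("affinity kernel matches a hand-evaluated oracle on a 1-D fixture", {
  pts <- c(0, 1, 2, 10)
  data <- matrix(pts, 4, 1, dimnames = list(paste0("s", 1:4), "f"))
  params <- fusion_params(k = 2, alpha = 0.5)
  w <- build_affinity(data, params)

  # oracle: standardize, distances, kNN means (k = 2, self excluded)
  z <- (pts - mean(pts)) / sd(pts)
  d <- abs(outer(z, z, "-"))
  knn_mean <- sapply(1:4, function(i) mean(sort(d[i, -i])[1:2]))
  eps <- (outer(knn_mean, knn_mean, "+") + d) / 3
  expected <- exp(-d^2 / (0.5 * eps))
  expected <- (expected + t(expected)) / 2
  expect_equal(unname(w), expected, tolerance = 1e-10)
  expect_equal(unname(diag(w)), rep(1, 4))

  # identical samples: W = 1
  dup <- matrix(c(1, 1, 5, 9), 4, 1, dimnames = list(paste0("s", 1:4), "f"))
  wd <- build_affinity(dup, params)
  expect_equal(unname(wd[1, 2]), 1)
})

test_that("affinities are symmetric and positive on random data", {
  withr::with_seed(42, {
    data <- matrix(rnorm(20 * 50), 20, 50,
                   dimnames = list(paste0("s", 1:20), NULL))
    w <- build_affinity(data, fusion_params(k = 5))
    expect_lt(max(abs(w - t(w))), 1e-12)
    expect_true(all(w > 0 & w <= 1))
  })
})

test_that("fusion is level-order invariant and permutation equivariant", {
  withr::with_seed(43, {
    d1 <- matrix(rnorm(20 * 30), 20, 30, dimnames = list(paste0("s", 1:20), NULL))
    d2 <- matrix(rnorm(20 * 30), 20, 30, dimnames = list(paste0("s", 1:20), NULL))
    params <- fusion_params(k = 5, t = 10)
    w1 <- build_affinity(d1, params); w2 <- build_affinity(d2, params)
    f12 <- snf_fuse(list(w1, w2), params)
    f21 <- snf_fuse(list(w2, w1), params)
    expect_equal(unclass(f12), unclass(f21), tolerance = 1e-8)
    expect_true(all(f12 >= 0))
    expect_lt(max(abs(f12 - t(f12))), 1e-10)

    perm <- sample(20)
    fp <- snf_fuse(list(w1[perm, perm], w2[perm, perm]), params)
    expect_equal(unclass(fp), unclass(f12)[perm, perm], tolerance = 1e-8)

    expect_error(snf_fuse(list(w1), params), "2 affinity levels")
    wbad <- w2; rownames(wbad)[1] <- "zz"
    expect_error(snf_fuse(list(w1, wbad), params), "same sample ids")
  })
})

test_that("fusion sharpens planted block structure", {
  withr::with_seed(44, {
    block <- rep(1:3, each = 7)
    mk_level <- function() {
      centers <- matrix(rnorm(3 * 10, sd = 3), 3, 10)
      data <- centers[block, ] + matrix(rnorm(21 * 10), 21, 10)
      rownames(data) <- paste0("s", 1:21)
      build_affinity(data, fusion_params(k = 5, t = 10))
    }
    fused <- snf_fuse(list(mk_level(), mk_level()), fusion_params(k = 5, t = 10))
    within <- mean(fused[outer(block, block, "==") & !diag(21)])
    between <- mean(fused[outer(block, block, "!=")])
    expect_gt(within, between)
  })
})

test_that("fusion iterates settle down over the final iterations", {
  cc <- generate_cohort(tiny_config(seed = 15, n_subjects = 16))
  irr <- cc$cohort$samples$sample_id[cc$cohort$samples$condition == "irradiated"]
  med <- cc$cohort$subjects$med
  expr <- log2(cc$cohort$expression[, irr] + 1)
  meth <- beta_to_m(cc$cohort$methylation_beta[, irr])
  p0 <- fusion_params(k = 5)
  w <- list(build_affinity(t(prefilter_by_med_correlation(expr, med, 0.2)), p0),
            build_affinity(t(prefilter_by_med_correlation(meth, med, 0.2)), p0))
  fused_at <- lapply(14:20, function(tt) {
    unclass(snf_fuse(w, fusion_params(k = 5, t = tt)))
  })
  deltas <- sapply(2:7, function(i) max(abs(fused_at[[i]] - fused_at[[i - 1]])))
  expect_true(all(diff(deltas[3:6]) <= 1e-8))
})

test_that("spectral clustering is exact on disconnected networks", {
  block <- rep(1:3, times = c(4, 5, 6))
  n <- length(block)
  w <- matrix(0, n, n, dimnames = list(paste0("s", 1:n), paste0("s", 1:n)))
  w[outer(block, block, "==")] <- 0.8
  diag(w) <- 1
  labels <- spectral_cluster(w, 3, seed = 7)
  expect_equal(adjusted_rand_index(labels, block), 1)
  # canonical labels: first sample in cluster 1, clusters by first occurrence
  expect_equal(unname(labels), block)

  expect_error(spectral_cluster(w, 1), "n_clusters")
  w_iso <- w; w_iso["s1", ] <- 0; w_iso[, "s1"] <- 0
  expect_error(spectral_cluster(w_iso, 3), "s1")
})

test_that("eigen-gap estimation finds components and respects the tie rule", {
  block <- rep(1:3, each = 5)
  n <- 15
  w <- matrix(0, n, n, dimnames = list(paste0("s", 1:n), paste0("s", 1:n)))
  w[outer(block, block, "==")] <- 0.9
  diag(w) <- 1
  est <- estimate_cluster_number(w, 2, 5)
  expect_equal(est$best_k, 3L)
  # disconnected 3-component graph: lambda_1..3 = 0, lambda_4 > 0
  lam_gap <- est$eigengaps$eigengap[est$eigengaps$k == 3]
  expect_gt(lam_gap, 0.5)

  # complete uniform graph: all candidate gaps equal -> smallest K wins
  u <- matrix(1, 10, 10, dimnames = list(paste0("s", 1:10), paste0("s", 1:10)))
  est_u <- estimate_cluster_number(u, 2, 5)
  expect_equal(est_u$best_k, 2L)
  expect_lt(diff(range(est_u$eigengaps$eigengap)), 1e-10)
})

test_that("subtype recovery degrades monotonically as the planted effect vanishes", {
  aris <- sapply(c(1.5, 0.5, 0), function(eff) {
    cc <- generate_cohort(cohort_config(seed = 10, subtype_effect = eff))
    st <- subtype_cohort(cc$cohort, n_clusters = 3, seed = 5)
    truth <- cc$cohort$subjects$true_subtype[
      match(st$assignment$subject_id, cc$cohort$subjects$subject_id)]
    adjusted_rand_index(st$assignment$subtype, truth)
  })
  expect_gte(aris[1], 0.8)
  expect_true(all(diff(aris) <= 0.05)) # non-increasing up to noise
  # residual structure at zero subtype effect comes from the MED-linked
  # features alone and must be visibly weaker
  expect_lt(aris[3], aris[1] - 0.1)
})
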