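make_diff_tbl <- function(ids, effect, q) {
  tibble::tibble(feature_id = ids, effect = effect, t_statistic = 0,
                 p_value = q, q_value = q, degenerate = FALSE)
}

test_that("DEMG selection enforces every threshold including the CpG count", {
  links <- tibble::tibble(
    cpg_id = paste0("cg", 1:4),
    gene_id = "G1",
    region_class = c("Enhancer", "TSS200", "Exon", "Intergenic")
  )
  manifest <- manifest_from_links(paste0("cg", 1:4), links)
  meth <- make_diff_tbl(paste0("cg", 1:4), effect = c(-0.5, -0.4, 0.3, -0.9),
                        q = c(0.01, 0.01, 0.01, 0.01))
  expr3 <- make_diff_tbl("G1", effect = 0.6, q = 0.01)
  res <- select_demgs(expr3, meth, manifest)
  # cg4 is intergenic: exactly 3 qualifying CpGs -> DEMG
  expect_equal(res$genes$n_qualifying_cpgs, 3L)
  expect_true(res$genes$demg)

  # drop one qualifying CpG below the effect threshold -> 2 CpGs, not a DEMG
  meth2 <- meth
  meth2$effect[3] <- 0.1
  res2 <- select_demgs(expr3, meth2, manifest)
  expect_equal(res2$genes$n_qualifying_cpgs, 2L)
  expect_false(res2$genes$demg)

  # expression effect below 0.5 -> never a DEMG
  expr_weak <- make_diff_tbl("G1", effect = 0.4, q = 0.01)
  expect_false(select_demgs(expr_weak, meth, manifest)$genes$demg)
})

test_that("DEMG summary fractions count up- and downregulated genes separately", {
  genes <- paste0("G", 1:20)
  direction <- rep(c(1, -1), each = 10)
  expr <- make_diff_tbl(genes, effect = direction * 0.8, q = 0.01)
  # give 3 up-genes and 4 down-genes three qualifying CpGs each
  demg_genes <- c(genes[1:3], genes[11:14])
  links <- do.call(rbind, lapply(demg_genes, function(g) {
    tibble::tibble(cpg_id = paste0(g, "_c", 1:3), gene_id = g,
                   region_class = "Enhancer")
  }))
  manifest <- manifest_from_links(unique(links$cpg_id), links)
  meth <- make_diff_tbl(links$cpg_id, effect = -0.5, q = 0.01)
  res <- suppressWarnings(select_demgs(expr, meth, manifest))
  s <- res$summary
  expect_equal(s$fraction_demg[s$direction == "up"], 0.30)
  expect_equal(s$fraction_demg[s$direction == "down"], 0.40)
})

test_that("DEMG selection equals a brute-force scan on a random fixture", {
  withr::with_seed(11, {
    genes <- paste0("G", 1:30)
    cpgs <- paste0("cg", 1:80)
    links <- tibble::tibble(
      cpg_id = sample(cpgs, 120, replace = TRUE),
      gene_id = sample(genes, 120, replace = TRUE),
      region_class = sample(c("Enhancer", "TSS200", "TSS1500", "Exon",
                              "Intergenic"), 120, replace = TRUE)
    ) |> dplyr::distinct(cpg_id, gene_id, .keep_all = TRUE)
    manifest <- manifest_from_links(cpgs, links)
    expr <- make_diff_tbl(genes, effect = rnorm(30, 0, 0.8),
                          q = runif(30, 0, 0.2))
    meth <- make_diff_tbl(cpgs, effect = rnorm(80, 0, 0.4),
                          q = runif(80, 0, 0.2))
    crit <- demg_criteria(min_cpgs = 2)
    res <- suppressWarnings(select_demgs(expr, meth, manifest, crit))
    brute <- demg_bruteforce(expr, meth, links, crit)
    expect_equal(setNames(res$genes$demg, res$genes$gene_id),
                 brute[res$genes$gene_id])
  })
})

test_that("regional aggregation averages member CpGs per gene and class", {
  links <- tibble::tibble(
    cpg_id = c("cg1", "cg2", "cg2", "cg3"),
    gene_id = c("G1", "G1", "G2", "G2"),
    region_class = "Enhancer"
  )
  manifest <- manifest_from_links(c("cg1", "cg2", "cg3"), links)
  m <- matrix(c(1, 3, 5,
                2, 4, 6), nrow = 3,
              dimnames = list(c("cg1", "cg2", "cg3"), c("s1", "s2")))
  agg <- aggregate_regional_methylation(m, manifest, "Enhancer")
  # G1 = mean(cg1, cg2); G2 = mean(cg2, cg3); cg2 contributes to both
  expect_equal(agg["G1", ], c(s1 = 2, s2 = 3))
  expect_equal(agg["G2", ], c(s1 = 4, s2 = 5))
  # single-CpG gene: row equals that CpG
  single <- manifest_from_links("cg1", links[1, ])
  agg1 <- aggregate_regional_methylation(m["cg1", , drop = FALSE], single,
                                         "Enhancer")
  expect_equal(agg1["G1", ], m["cg1", ])
  expect_warning(aggregate_regional_methylation(m, manifest, "Exon"),
                 "No CpGs")
})

test_that("expression-methylation regression matches a closed-form OLS oracle", {
  x <- c(0, 1, 2, 3, 4)
  y <- c(1, 1.9, 3.2, 3.9, 5.1)
  links <- tibble::tibble(cpg_id = "cg1", gene_id = "G1",
                          region_class = "TSS200")
  manifest <- manifest_from_links("cg1", links)
  meth <- matrix(x, 1, 5, dimnames = list("cg1", paste0("s", 1:5)))
  expr <- matrix(y, 1, 5, dimnames = list("G1", paste0("s", 1:5)))
  rec <- correlate_expression_methylation(expr, meth, manifest,
                                          classes = "TSS200")
  fit <- lm(y ~ x)
  expect_equal(rec$slope, unname(coef(fit)[2]), tolerance = 1e-10)
  expect_equal(rec$pearson_r, cor(x, y), tolerance = 1e-10)
  expect_equal(rec$p_value, summary(fit)$coefficients[2, 4],
               tolerance = 1e-10)

  # perfect line: r = 1, tiny p
  expr2 <- matrix(2 * (1:8), 1, 8, dimnames = list("G1", paste0("s", 1:8)))
  meth2 <- matrix(1:8, 1, 8, dimnames = list("cg1", paste0("s", 1:8)))
  rec2 <- correlate_expression_methylation(expr2, meth2, manifest,
                                           classes = "TSS200")
  expect_equal(rec2$pearson_r, 1)
  expect_lt(rec2$p_value, 1e-10)

  # constant expression: pair skipped
  expr3 <- matrix(5, 1, 8, dimnames = list("G1", paste0("s", 1:8)))
  rec3 <- correlate_expression_methylation(expr3, meth2, manifest,
                                           classes = "TSS200")
  expect_equal(nrow(rec3), 0)
  expect_equal(attr(rec3, "n_skipped"), 1L)
})

test_that("correlation q-values reproduce bh_adjust over the pooled tests", {
  cc <- generate_cohort(tiny_config(seed = 12))
  ann <- generate_annotations(tiny_config(seed = 12))
  rec <- correlate_expression_methylation(
    log2(cc$cohort$expression + 1), beta_to_m(cc$cohort$methylation_beta),
    ann$manifest
  )
  expect_gt(nrow(rec), 10)
  expect_equal(rec$q_value, bh_adjust(rec$p_value))
})

test_that("block concordance computes membership means and handles empty blocks", {
  links <- tibble::tibble(cpg_id = character(), gene_id = character(),
                          region_class = character())
  manifest <- manifest_from_links(paste0("cg", 1:5), links)
  # positions are 100,200,...,500 on chr1
  blocks <- tibble::tibble(
    block_id = c("b1", "b2", "b3"),
    chromosome = c("chr1", "chr1", "chrX"),
    start = c(50L, 350L, 0L), end = c(250L, 450L, 100L),
    reference_delta = c(-0.8, 0.5, 0.1)
  )
  meth <- make_diff_tbl(paste0("cg", 1:5),
                        effect = c(-0.4, -0.2, 0.3, 0.6, 0.1),
                        q = c(0.01, 0.01, 0.9, 0.9, 0.9))
  res <- suppressWarnings(block_concordance(meth, manifest, blocks))
  b1 <- res$blocks[res$blocks$block_id == "b1", ]
  expect_equal(b1$n_sig_cpgs, 2L)
  expect_equal(b1$mean_effect, -0.3)
  expect_true(b1$sign_match)
  # b2 has no significant CpGs: reported but excluded from the correlation
  expect_equal(res$blocks$n_sig_cpgs[res$blocks$block_id == "b2"], 0L)
  expect_equal(res$n_evaluated, 1L)
  # b3 on an absent chromosome: dropped with a warning
  expect_false("b3" %in% res$blocks$block_id)
})

test_that("planted DEMGs and concordant blocks are recovered at default scale", {
  cc <- default_cohort()
  ann <- default_annotations()
  d <- default_differential()

  res <- suppressWarnings(select_demgs(d$expression, d$methylation,
                                       ann$manifest))
  truth <- cc$truth$demg_genes$gene_id
  called <- res$genes$gene_id[res$genes$demg]
  sensitivity <- mean(truth %in% called)
  fdr <- mean(!(called %in% truth))
  expect_gte(sensitivity, 0.8)
  expect_lte(fdr, 0.2)

  conc_ids <- ann$block_truth$block_id[ann$block_truth$concordant]
  bc <- block_concordance(d$methylation, ann$manifest,
                          ann$blocks |> dplyr::filter(block_id %in% conc_ids))
  expect_true(all(bc$blocks$sign_match))
  expect_gte(bc$pearson_r, 0.9)
})
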