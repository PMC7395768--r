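test_that("generation is deterministic and honours the null-effect case", {
  a <- generate_cohort(tiny_config(seed = 4))
  b <- generate_cohort(tiny_config(seed = 4))
  expect_identical(a$cohort$expression, b$cohort$expression)
  expect_identical(a$cohort$methylation_beta, b$cohort$methylation_beta)
  expect_identical(a$cohort$subjects, b$cohort$subjects)
  expect_identical(a$truth$affected_cpgs, b$truth$affected_cpgs)

  null_cfg <- tiny_config(seed = 2, frac_cpgs_affected = 0,
                          frac_genes_affected = 0, subtype_effect = 0)
  cc <- generate_cohort(null_cfg)
  expect_equal(nrow(cc$truth$affected_cpgs), 0)
  expect_equal(nrow(cc$truth$affected_genes), 0)
  # without planted effects, paired differences are pure noise: mean absolute
  # per-CpG difference stays near sqrt(2/pi) * sqrt(2) * noise_sd
  m <- beta_to_m(cc$cohort$methylation_beta)
  irr <- grepl("_irr$", colnames(m))
  d <- rowMeans(m[, irr]) - rowMeans(m[, !irr])
  expect_lt(max(abs(d)), 1.5)
})

test_that("cohort matrices respect their domain invariants", {
  cc <- generate_cohort(tiny_config(seed = 5))
  expect_true(all(cc$cohort$methylation_beta > 0 &
                    cc$cohort$methylation_beta < 1))
  expect_true(all(cc$cohort$expression >= 0))
  counts <- table(cc$cohort$samples$subject_id)
  expect_true(all(counts == 2))
  expect_true(all(cc$cohort$subjects$true_subtype %in% 1:3))
  # every planted id exists in the corresponding matrix
  expect_true(all(cc$truth$affected_cpgs$cpg_id %in%
                    rownames(cc$cohort$methylation_beta)))
  expect_true(all(cc$truth$affected_genes$gene_id %in%
                    rownames(cc$cohort$expression)))
})

test_that("planted hypomethylation fraction is exact and graded by island relation", {
  cc <- default_cohort()
  aff <- cc$truth$affected_cpgs
  n_aff <- nrow(aff)
  expect_equal(n_aff, round(0.25 * 20000))
  frac_hypo <- mean(aff$delta_m < 0)
  expect_lte(abs(frac_hypo - 0.651), 1 / n_aff)
  expect_lt(abs(frac_hypo - 0.651), 0.01)
  per_rel <- tapply(aff$delta_m < 0, aff$island_relation, mean)
  per_rel <- per_rel[c("OpenSea", "Shelf", "Shore", "Island")]
  expect_true(all(diff(per_rel) >= -0.02))
})

test_that("configuration validation rejects malformed study designs", {
  expect_error(cohort_config(subtype_proportions = c(0.5, 0.5, 0.5)),
               "simplex")
  expect_error(cohort_config(med_means = c(200, 150, 100)), "increasing")
  expect_error(cohort_config(frac_cpgs_affected = 1.2), "\\[0, 1\\]")
  expect_error(cohort_config(island_gradient = c(OpenSea = 0.9, Shelf = 0.5,
                                                 Shore = 0.6, Island = 0.7)),
               "non-decreasing")
})

test_that("realized paired differences track planted effects and MED features carry signal", {
  cc <- default_cohort()
  cohort <- cc$cohort
  irr <- grepl("_irr$", colnames(cohort$expression))

  el <- log2(cohort$expression + 1)
  d_expr <- rowMeans(el[, irr]) - rowMeans(el[, !irr])
  strong <- cc$truth$affected_genes |>
    dplyr::filter(abs(log2fc) > 4 * 0.5)
  if (nrow(strong) > 0) {
    expect_true(all(sign(d_expr[strong$gene_id]) == sign(strong$log2fc)))
  }
  m <- beta_to_m(cohort$methylation_beta)
  d_meth <- rowMeans(m[, irr]) - rowMeans(m[, !irr])
  strong_c <- cc$truth$affected_cpgs |>
    dplyr::filter(abs(delta_m) > 4 * 0.4)
  expect_gte(nrow(strong_c), 5)
  expect_true(all(sign(d_meth[strong_c$cpg_id]) == sign(strong_c$delta_m)))

  med <- cohort$subjects$med[match(cohort$samples$subject_id,
                                   cohort$subjects$subject_id)]
  mf <- cc$truth$med_features
  r_expr <- abs(cor(t(el[mf$feature_id[mf$level == "expression"], ,
                         drop = FALSE]), med))
  r_meth <- abs(cor(t(m[mf$feature_id[mf$level == "methylation"], ,
                        drop = FALSE]), med))
  expect_true(all(r_expr > 0.5))
  expect_true(all(r_meth > 0.5))
})

test_that("annotations are structurally valid and consistent with the planted truth", {
  cfg <- tiny_config(seed = 3, n_cpgs = 10, n_genes = 20,
                     genes_per_subtype_pathway = 1, cpgs_per_subtype_gene = 1,
                     n_med_predictive_features = 2, n_blocks = 0,
                     n_concordant_blocks = 0, shared_pathway_size = 2,
                     null_set_size = 3)
  ann <- generate_annotations(cfg)
  expect_equal(nrow(ann$manifest), 10)
  for (ch in unique(ann$manifest$chromosome)) {
    pos <- ann$manifest$position[ann$manifest$chromosome == ch]
    expect_true(all(diff(pos) > 0))
  }

  cc <- default_cohort()
  ann_d <- default_annotations()
  links <- manifest_links(ann_d$manifest)
  link_counts <- table(links$gene_id[links$cpg_id %in% links$cpg_id])
  demg <- cc$truth$demg_genes$gene_id
  n_linked <- vapply(demg, function(g) sum(links$gene_id == g), numeric(1))
  expect_true(all(n_linked >= 3))

  # concordant blocks: reference delta sign equals mean planted delta of members
  bt <- ann_d$block_truth |> dplyr::filter(concordant)
  members <- cpgs_in_blocks(ann_d$manifest, bt)
  planted <- cc$truth$affected_cpgs
  for (b in bt$block_id) {
    cpgs <- members$cpg_id[members$block_id == b]
    d <- planted$delta_m[planted$cpg_id %in% cpgs]
    expect_equal(sign(bt$reference_delta[bt$block_id == b]),
                 sign(mean(d)))
  }
})
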