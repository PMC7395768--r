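REGION_CLASSES <- c("TSS200", "TSS1500", "Exon", "Enhancer", "Intergenic")
ISLAND_RELATIONS <- c("Island", "Shore", "Shelf", "OpenSea")

# All structural randomization (annotations + planted truth) happens here
# under a single seeded stream, so generate_cohort() and
# generate_annotations() called with the same config agree exactly.
plant_cohort_structure <- function(config) {
  withr::with_seed(config$seed, plant_cohort_structure_impl(config))
}

plant_cohort_structure_impl <- function(config) {
  n_cpgs <- config$n_cpgs
  n_genes <- config$n_genes
  gene_ids <- sprintf("G%05d", seq_len(n_genes))

  # genomic skeleton: chromosomes weighted roughly by physical size, positions
  # strictly increasing within each chromosome, ids assigned in genome order
  chr_weights <- 23 - seq_len(22)
  chrom_idx <- sample.int(22, n_cpgs, replace = TRUE, prob = chr_weights)
  pos <- integer(n_cpgs)
  for (ch in unique(chrom_idx)) {
    idx <- which(chrom_idx == ch)
    pos[idx] <- sort(sample.int(2e8, length(idx)))
  }
  ord <- order(chrom_idx, pos)
  chrom_idx <- chrom_idx[ord]
  pos <- pos[ord]
  cpg_ids <- sprintf("cg%08d", seq_len(n_cpgs))
  chromosome <- paste0("chr", chrom_idx)
  island_relation <- sample(names(config$island_relation_probs), n_cpgs,
                            replace = TRUE, prob = config$island_relation_probs)

  # ---- planted CpG effects: exact hypo/hyper counts per island relation ----
  n_affected <- round(config$frac_cpgs_affected * n_cpgs)
  affected_idx <- sort(sample.int(n_cpgs, n_affected))
  sign_vec <- integer(n_affected)
  if (n_affected > 0) {
    n_hypo <- round(config$frac_hypo_among_affected * n_affected)
    rel_levels <- c("OpenSea", "Shelf", "Shore", "Island")
    rel_aff <- factor(island_relation[affected_idx], levels = rel_levels)
    m_r <- as.integer(table(rel_aff))
    g_r <- unname(config$island_gradient[rel_levels])
    h_r <- apportion_counts(n_hypo, w = g_r * m_r, cap = m_r)
    sign_vec <- rep(1L, n_affected)
    for (r in seq_along(rel_levels)) {
      members <- which(as.integer(rel_aff) == r)
      if (h_r[r] > 0) {
        sign_vec[sample(members, h_r[r])] <- -1L
      }
    }
  }
  magnitude <- rlnorm(n_affected, config$effect_size_params$meth_meanlog,
                      config$effect_size_params$meth_sdlog)
  affected_cpgs <- tibble(
    cpg_id = cpg_ids[affected_idx],
    island_relation = island_relation[affected_idx],
    delta_m = sign_vec * magnitude
  )

  # ---- planted gene effects ----
  n_gaff <- round(config$frac_genes_affected * n_genes)
  gaff_idx <- sort(sample.int(n_genes, n_gaff))
  gsign <- sample(c(-1L, 1L), n_gaff, replace = TRUE)
  gmag <- rlnorm(n_gaff, config$effect_size_params$expr_meanlog,
                 config$effect_size_params$expr_sdlog)
  affected_genes <- tibble(gene_id = gene_ids[gaff_idx],
                           log2fc = gsign * gmag)

  # ---- DEMG coupling: pick affected genes, attach already-signed affected
  # CpGs of one common sign and solid magnitude, flip the gene against them ----
  n_demg <- round(config$frac_demg * n_gaff)
  demg_links <- tibble(gene_id = character(), cpg_id = character(),
                       region_class = character())
  demg_genes <- tibble(gene_id = character(), log2fc = double(),
                       cpg_sign = integer())
  if (n_demg > 0) {
    demg_gene_ids <- sample(affected_genes$gene_id, n_demg)
    pool <- affected_cpgs |>
      filter(abs(.data$delta_m) > 0.45) |>
      mutate(used = FALSE)
    links <- vector("list", n_demg)
    signs <- integer(n_demg)
    for (i in seq_len(n_demg)) {
      k <- sample(seq(config$demg_cpg_range[1], config$demg_cpg_range[2]), 1)
      s <- if (runif(1) < config$frac_hypo_among_affected) -1L else 1L
      avail <- which(!pool$used & sign(pool$delta_m) == s)
      if (length(avail) < k) {
        s <- -s
        avail <- which(!pool$used & sign(pool$delta_m) == s)
      }
      pick <- sample(avail, min(k, length(avail)))
      pool$used[pick] <- TRUE
      signs[i] <- s
      links[[i]] <- tibble(
        gene_id = demg_gene_ids[i],
        cpg_id = pool$cpg_id[pick],
        region_class = sample(c("Enhancer", "TSS200", "TSS1500"), length(pick),
                              replace = TRUE, prob = c(0.5, 0.3, 0.2))
      )
    }
    demg_links <- bind_rows(links)
    # expression change anti-correlated with the planted methylation change,
    # with magnitude safely above the DEMG log2FC threshold
    demg_fc <- -signs * (0.7 + rlnorm(n_demg, log(0.3), 0.5))
    demg_genes <- tibble(gene_id = demg_gene_ids, log2fc = demg_fc,
                         cpg_sign = signs)
    affected_genes$log2fc[match(demg_gene_ids, affected_genes$gene_id)] <- demg_fc
  }

  # ---- subtype-specific response pathways (expression + linked CpGs) ----
  unaffected_genes <- setdiff(gene_ids, affected_genes$gene_id)
  n_sub_genes <- 3 * config$genes_per_subtype_pathway
  sub_gene_ids <- sample(unaffected_genes, n_sub_genes)
  subtype_pathways <- tibble(
    set_name = rep(sprintf("SUBTYPE%d_RESPONSE", 1:3),
                   each = config$genes_per_subtype_pathway),
    subtype = rep(1:3, each = config$genes_per_subtype_pathway),
    gene_id = sub_gene_ids,
    effect = sample(c(-1, 1), n_sub_genes, replace = TRUE) * config$subtype_effect
  )
  free_cpgs <- setdiff(cpg_ids, affected_cpgs$cpg_id)
  sub_cpg_ids <- sample(free_cpgs,
                        n_sub_genes * config$cpgs_per_subtype_gene)
  subtype_cpgs <- tibble(
    cpg_id = sub_cpg_ids,
    gene_id = rep(subtype_pathways$gene_id, each = config$cpgs_per_subtype_gene),
    subtype = rep(subtype_pathways$subtype, each = config$cpgs_per_subtype_gene),
    effect = rep(sample(c(-1, 1), n_sub_genes, replace = TRUE) *
                   config$subtype_effect, each = config$cpgs_per_subtype_gene),
    region_class = sample(c("TSS200", "Enhancer"),
                          n_sub_genes * config$cpgs_per_subtype_gene,
                          replace = TRUE)
  )

  # ---- MED-predictive features (baseline linear in MED, both conditions) ----
  med_gene_pool <- setdiff(unaffected_genes, sub_gene_ids)
  med_genes <- sample(med_gene_pool, config$n_med_predictive_features)
  med_cpg_pool <- setdiff(free_cpgs, sub_cpg_ids)
  med_cpgs <- sample(med_cpg_pool, config$n_med_predictive_features)
  n_mf <- config$n_med_predictive_features
  med_features <- tibble(
    level = rep(c("expression", "methylation"), each = n_mf),
    feature_id = c(med_genes, med_cpgs),
    slope = sample(c(-1, 1), 2 * n_mf, replace = TRUE) * runif(2 * n_mf, 0.8, 1.2)
  )

  # ---- background gene links (0-2 per CpG), planted links respected ----
  planted_links <- bind_rows(
    demg_links,
    subtype_cpgs |> select("cpg_id", "gene_id", "region_class")
  )
  planted_per_cpg <- table(planted_links$cpg_id)
  n_extra <- sample(0:2, n_cpgs, replace = TRUE, prob = c(0.75, 0.22, 0.03))
  already <- as.integer(planted_per_cpg[cpg_ids])
  already[is.na(already)] <- 0L
  n_extra <- pmin(n_extra, 2L - already)
  tot_extra <- sum(n_extra)
  background_links <- tibble(
    cpg_id = rep(cpg_ids, n_extra),
    gene_id = sample(gene_ids, tot_extra, replace = TRUE),
    region_class = sample(REGION_CLASSES, tot_extra, replace = TRUE,
                          prob = c(0.15, 0.15, 0.25, 0.30, 0.15))
  )
  gene_links <- bind_rows(planted_links, background_links) |>
    dplyr::distinct(.data$cpg_id, .data$gene_id, .keep_all = TRUE)

  manifest <- tibble(
    cpg_id = cpg_ids, chromosome = chromosome, position = pos,
    island_relation = island_relation
  )

  # ---- genomic reference blocks ----
  blocks <- plant_blocks(config, manifest, affected_cpgs)

  # ---- gene-set collection ----
  up_pool <- affected_genes |> filter(.data$log2fc > 0)
  shared <- sample(up_pool$gene_id, min(config$shared_pathway_size, nrow(up_pool)))
  null_pool <- setdiff(med_gene_pool, med_genes)
  null_sets <- lapply(seq_len(config$n_null_sets), function(i) {
    sample(null_pool, min(config$null_set_size, length(null_pool)))
  })
  names(null_sets) <- sprintf("NULL_SET_%02d", seq_len(config$n_null_sets))
  gene_sets <- c(
    split(subtype_pathways$gene_id, subtype_pathways$set_name),
    list(UV_SHARED_RESPONSE = shared),
    null_sets
  )

  list(
    gene_ids = gene_ids, manifest = manifest, gene_links = gene_links,
    affected_cpgs = affected_cpgs, affected_genes = affected_genes,
    demg_genes = demg_genes, demg_links = demg_links,
    subtype_pathways = subtype_pathways, subtype_cpgs = subtype_cpgs,
    med_features = med_features, blocks = blocks, gene_sets = gene_sets
  )
}

# contiguous CpG windows; the concordant subset sits on coherent planted
# methylation change and records a same-sign (amplified) reference delta,
# emulating regions described in chronically sun-exposed skin
plant_blocks <- function(config, manifest, affected_cpgs) {
  if (config$n_blocks == 0) {
    return(tibble(block_id = character(), chromosome = character(),
                  start = integer(), end = integer(),
                  reference_delta = double(), concordant = logical()))
  }
  aff <- match(affected_cpgs$cpg_id, manifest$cpg_id)
  delta_by_row <- rep(NA_real_, nrow(manifest))
  delta_by_row[aff] <- affected_cpgs$delta_m

  window_for <- function(anchor_row) {
    ch <- manifest$chromosome[anchor_row]
    rows <- which(manifest$chromosome == ch)
    at <- match(anchor_row, rows)
    lo <- max(1, at - 15); hi <- min(length(rows), at + 15)
    rows[lo:hi]
  }

  n_conc <- min(config$n_concordant_blocks, config$n_blocks)
  conc <- list(); tries <- 0
  while (length(conc) < n_conc && tries < 4000 && length(aff) > 0) {
    tries <- tries + 1
    rows <- window_for(sample(aff, 1))
    d <- delta_by_row[rows]
    d <- d[!is.na(d)]
    if (length(d) >= 3 && abs(mean(d)) >= 0.25) {
      conc[[length(conc) + 1]] <- tibble(
        chromosome = manifest$chromosome[rows[1]],
        start = min(manifest$position[rows]) - 1L,
        end = max(manifest$position[rows]),
        reference_delta = 2.5 * mean(d) + rnorm(1, 0, 0.05),
        concordant = TRUE
      )
    }
  }
  n_null <- config$n_blocks - length(conc)
  null_blocks <- lapply(seq_len(n_null), function(i) {
    rows <- window_for(sample.int(nrow(manifest), 1))
    tibble(
      chromosome = manifest$chromosome[rows[1]],
      start = min(manifest$position[rows]) - 1L,
      end = max(manifest$position[rows]),
      reference_delta = rnorm(1, 0, 0.5),
      concordant = FALSE
    )
  })
  out <- bind_rows(bind_rows(conc), bind_rows(null_blocks))
  out$block_id <- sprintf("block_%03d", seq_len(nrow(out)))
  select(out, "block_id", "chromosome", "start", "end",
         "reference_delta", "concordant")
}

#' Generate a synthetic paired multi-omics cohort with ground truth
#'
#' Simulates a paired (control vs irradiated, same subject) cohort with the
#' statistical structure described in [cohort_config()]. Methylation is
#' generated on the latent M scale (Gaussian baseline by island relation,
#' subject effect, residual noise, planted irradiation effects) and mapped to
#' Beta values by the logistic transform `Beta = 2^M / (1 + 2^M)`; expression
#' is generated as Gaussian log2(TPM+1) and exponentiated back to the TPM
#' scale. All planted effects are recorded in a ground-truth ledger for
#' recovery testing.
#'
#' @param config A [cohort_config()] object.
#' @return A list with components `cohort` (class `photomics_cohort`: matrices
#'   `expression` (gene x sample, TPM) and `methylation_beta` (CpG x sample,
#'   Beta in (0,1)), tibbles `samples` and `subjects`) and `truth` (class
#'   `photomics_truth`: planted CpG/gene effects, DEMG links, MED-predictive
#'   features, subtype pathways, block table).
#' @export
#' @examples
#' cc <- generate_cohort(cohort_config(n_subjects = 6, n_genes = 50,
#'                                     n_cpgs = 200, seed = 1))
#' dim(cc$cohort$expression)
generate_cohort <- function(config) {
  config <- validate_cohort_config(config)
  str <- plant_cohort_structure(config)
  withr::with_seed(derive_seed(config$seed, 7L), {
    build_cohort_matrices(config, str)
  })
}

build_cohort_matrices <- function(config, str) {
  ns <- config$n_subjects
  subject_id <- sprintf("S%02d", seq_len(ns))

  counts <- apportion_counts(ns, config$subtype_proportions, rep(ns, 3))
  subtype <- sample(rep(1:3, counts))
  med <- rnorm(ns, config$med_means[subtype], config$med_sd)
  med <- pmax(med, 10)
  # Fitzpatrick phototype as a noisy discretization of MED (poor concordance
  # with MED by design; cosmetic metadata only)
  fitzpatrick <- findInterval(med + rnorm(ns, 0, 25), c(112, 137, 175)) + 1L

  subjects <- tibble(subject_id = subject_id, med = med,
                     fitzpatrick = fitzpatrick, true_subtype = subtype)
  samples <- tibble(
    sample_id = c(paste0(subject_id, "_ctrl"), paste0(subject_id, "_irr")),
    subject_id = rep(subject_id, 2),
    condition = rep(c("control", "irradiated"), each = ns)
  ) |> arrange(.data$subject_id, .data$condition)

  subj_of <- match(samples$subject_id, subject_id)
  irr <- samples$condition == "irradiated"
  n_samp <- nrow(samples)
  med_center <- mean(config$med_means)
  med_scale <- (max(config$med_means) - min(config$med_means)) / 2
  med_z <- (med - med_center) / med_scale

  # ---- expression on log2(TPM+1) scale ----
  ng <- config$n_genes
  base_g <- runif(ng, 2, 8)
  subj_eff <- matrix(rnorm(ng * ns, 0, config$subject_sd[["expression"]]), ng, ns)
  ex <- base_g + subj_eff[, subj_of] +
    matrix(rnorm(ng * n_samp, 0, config$noise_sd[["expression"]]), ng, n_samp)
  gidx <- match(str$affected_genes$gene_id, str$gene_ids)
  if (length(gidx)) ex[gidx, irr] <- ex[gidx, irr] + str$affected_genes$log2fc
  sp <- str$subtype_pathways
  for (s in 1:3) {
    rows <- match(sp$gene_id[sp$subtype == s], str$gene_ids)
    cols <- which(irr & subtype[subj_of] == s)
    if (length(rows) && length(cols)) {
      ex[rows, cols] <- ex[rows, cols] + sp$effect[sp$subtype == s]
    }
  }
  mf <- str$med_features
  mg <- mf[mf$level == "expression", ]
  rows <- match(mg$feature_id, str$gene_ids)
  if (length(rows)) ex[rows, ] <- ex[rows, ] + outer(mg$slope, med_z[subj_of])
  ex <- pmax(ex, 0)
  expression <- 2^ex - 1
  dimnames(expression) <- list(str$gene_ids, samples$sample_id)

  # ---- methylation on latent M scale ----
  nc <- config$n_cpgs
  rel <- str$manifest$island_relation
  mu_by_rel <- c(Island = -2.5, Shore = -1, Shelf = 1, OpenSea = 2)
  mu_c <- rnorm(nc, mu_by_rel[rel], 1)
  subj_eff_m <- matrix(rnorm(nc * ns, 0, config$subject_sd[["methylation"]]), nc, ns)
  mm <- mu_c + subj_eff_m[, subj_of] +
    matrix(rnorm(nc * n_samp, 0, config$noise_sd[["methylation"]]), nc, n_samp)
  cidx <- match(str$affected_cpgs$cpg_id, str$manifest$cpg_id)
  if (length(cidx)) mm[cidx, irr] <- mm[cidx, irr] + str$affected_cpgs$delta_m
  sc <- str$subtype_cpgs
  for (s in 1:3) {
    rows <- match(sc$cpg_id[sc$subtype == s], str$manifest$cpg_id)
    cols <- which(irr & subtype[subj_of] == s)
    if (length(rows) && length(cols)) {
      mm[rows, cols] <- mm[rows, cols] + sc$effect[sc$subtype == s]
    }
  }
  mc <- mf[mf$level == "methylation", ]
  rows <- match(mc$feature_id, str$manifest$cpg_id)
  if (length(rows)) mm[rows, ] <- mm[rows, ] + outer(mc$slope, med_z[subj_of])
  methylation_beta <- 2^mm / (1 + 2^mm)
  dimnames(methylation_beta) <- list(str$manifest$cpg_id, samples$sample_id)

  cohort <- structure(
    list(expression = expression, methylation_beta = methylation_beta,
         samples = samples, subjects = subjects),
    class = "photomics_cohort"
  )
  truth <- structure(
    list(affected_cpgs = str$affected_cpgs,
         affected_genes = str$affected_genes,
         demg_genes = str$demg_genes, demg_links = str$demg_links,
         med_features = str$med_features,
         subtype_pathways = str$subtype_pathways,
         subtype_cpgs = str$subtype_cpgs,
         blocks = str$blocks),
    class = "photomics_truth"
  )
  list(cohort = cohort, truth = truth)
}

#' Generate annotations matching a synthetic cohort
#'
#' Produces the CpG manifest (coordinates, island relation, gene links with
#' functional region class), the gene-set collection (planted subtype
#' pathways, a shared UV response set, and random null sets) and the genomic
#' reference block table consistent with the cohort produced by
#' [generate_cohort()] under the same configuration.
#'
#' @param config A [cohort_config()] object.
#' @return A list with `manifest` (tibble: cpg_id, chromosome, position
#'   (1-based), island_relation, gene_links string `"GENE:CLASS;..."`),
#'   `gene_sets` (named list of character vectors) and `blocks` (tibble with
#'   0-based half-open `start`/`end` and `reference_delta`).
#' @export
generate_annotations <- function(config) {
  config <- validate_cohort_config(config)
  str <- plant_cohort_structure(config)
  links <- str$gene_links |>
    mutate(tag = paste0(.data$gene_id, ":", .data$region_class)) |>
    group_by(.data$cpg_id) |>
    summarise(gene_links = paste(.data$tag, collapse = ";"), .groups = "drop")
  manifest <- str$manifest |>
    left_join(links, by = "cpg_id") |>
    mutate(gene_links = dplyr::coalesce(.data$gene_links, ""))
  list(manifest = manifest, gene_sets = str$gene_sets,
       blocks = select(str$blocks, -"concordant"),
       block_truth = str$blocks)
}

#' @export
print.photomics_cohort <- function(x, ...) {
  cat("<photomics_cohort>\n")
  cat(sprintf("  %d genes x %d samples (TPM); %d CpGs x %d samples (Beta)\n",
              nrow(x$expression), ncol(x$expression),
              nrow(x$methylation_beta), ncol(x$methylation_beta)))
  cat(sprintf("  %d subjects, paired control/irradiated design\n",
              nrow(x$subjects)))
  invisible(x)
}

#' @export
print.photomics_truth <- function(x, ...) {
  cat("<photomics_truth>\n")
  cat(sprintf("  %d affected CpGs (%.1f%% hypo), %d affected genes, %d DEMGs\n",
              nrow(x$affected_cpgs),
              if (nrow(x$affected_cpgs)) 100 * mean(x$affected_cpgs$delta_m < 0) else NA,
              nrow(x$affected_genes), nrow(x$demg_genes)))
  invisible(x)
}
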