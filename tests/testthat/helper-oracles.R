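# Independent oracles used across tests. These deliberately avoid the code
# paths they are checking.

# literal Benjamini-Hochberg step-up: sort ascending, q_(i) = min_{j>=i}
# p_(j) * m / j, cap at 1, map back to input order
bh_stepup_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(ps[i:m] * m / (i:m))
  }
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

# brute-force DEMG scan over all (gene, CpG) pairs from a long link table
demg_bruteforce <- function(expr_diff, meth_diff, links, criteria) {
  out <- logical(nrow(expr_diff))
  names(out) <- expr_diff$feature_id
  for (i in seq_len(nrow(expr_diff))) {
    g <- expr_diff$feature_id[i]
    de <- expr_diff$q_value[i] < criteria$expr_q &&
      abs(expr_diff$effect[i]) > criteria$expr_abs_effect
    n_qual <- 0
    seen <- character(0)
    for (j in seq_len(nrow(links))) {
      if (links$gene_id[j] != g) next
      if (links$region_class[j] == "Intergenic") next
      cpg <- links$cpg_id[j]
      if (cpg %in% seen) next
      k <- match(cpg, meth_diff$feature_id)
      if (is.na(k)) next
      if (meth_diff$q_value[k] < criteria$cpg_q &&
          abs(meth_diff$effect[k]) > criteria$cpg_abs_effect) {
        n_qual <- n_qual + 1
        seen <- c(seen, cpg)
      }
    }
    out[i] <- de && n_qual >= criteria$min_cpgs
  }
  out
}

# build a paired sample table for matrices whose columns are
# S1_ctrl, S1_irr, S2_ctrl, ... in any order
paired_samples <- function(subject_ids) {
  tibble::tibble(
    sample_id = c(paste0(subject_ids, "_ctrl"), paste0(subject_ids, "_irr")),
    subject_id = rep(subject_ids, 2),
    condition = rep(c("control", "irradiated"), each = length(subject_ids))
  )
}

# a tiny manifest in the package's TSV shape from a long link table
manifest_from_links <- function(cpg_ids, links,
                                island_relation = "OpenSea") {
  link_str <- vapply(cpg_ids, function(cpg) {
    rows <- links[links$cpg_id == cpg, , drop = FALSE]
    if (nrow(rows) == 0) return("")
    paste(paste0(rows$gene_id, ":", rows$region_class), collapse = ";")
  }, character(1))
  tibble::tibble(
    cpg_id = cpg_ids,
    chromosome = "chr1",
    position = seq_along(cpg_ids) * 100L,
    island_relation = island_relation,
    gene_links = unname(link_str)
  )
}
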