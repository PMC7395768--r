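# Readers/writers for the plain-text formats the pipeline touches:
# TSV matrices, sample/subject metadata, the CpG manifest, MSigDB-dialect
# GMT, BED4+ reference blocks, YAML config and JSON ground truth.

read_matrix_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  ids <- df[[1]]
  if (anyDuplicated(ids)) {
    abort(sprintf("Duplicated row ids in %s: %s", path,
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ids
  storage.mode(m) <- "double"
  m
}

write_matrix_tsv <- function(m, path, id_col) {
  df <- tibble::as_tibble(m, rownames = id_col)
  readr::write_tsv(df, path, progress = FALSE)
}

#' Write a cohort to plain-text files
#'
#' Writes the expression matrix (TPM), methylation matrix (Beta), and the
#' sample/subject metadata tables as TSV into `dir`.
#'
#' @param cohort A `photomics_cohort`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, a named list of the file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    expression = file.path(dir, "expression_tpm.tsv"),
    methylation = file.path(dir, "methylation_beta.tsv"),
    samples = file.path(dir, "samples.tsv"),
    subjects = file.path(dir, "subjects.tsv")
  )
  write_matrix_tsv(cohort$expression, paths$expression, "gene_id")
  write_matrix_tsv(cohort$methylation_beta, paths$methylation, "cpg_id")
  readr::write_tsv(cohort$samples, paths$samples, progress = FALSE)
  readr::write_tsv(cohort$subjects, paths$subjects, progress = FALSE)
  invisible(paths)
}

#' Load and validate a paired cohort from TSV files
#'
#' Reads the expression/methylation matrices and metadata written by
#' [write_cohort()] (or equivalently structured files), verifies the paired
#' design (every subject has exactly one control and one irradiated sample,
#' and every matrix column is described in the sample table) and clamps Beta
#' values into the open interval (0, 1).
#'
#' @param paths Named list/vector with `expression`, `methylation`, `samples`,
#'   `subjects` file paths.
#' @param beta_clamp Half-width epsilon: Beta values are clamped into
#'   `[beta_clamp, 1 - beta_clamp]`. Values outside `[0, 1]` are an error.
#' @return A validated `photomics_cohort`.
#' @export
load_dataset <- function(paths, beta_clamp = 1e-6) {
  expression <- read_matrix_tsv(paths$expression)
  methylation <- read_matrix_tsv(paths$methylation)
  samples <- readr::read_tsv(paths$samples, show_col_types = FALSE,
                             progress = FALSE)
  subjects <- readr::read_tsv(paths$subjects, show_col_types = FALSE,
                              progress = FALSE)

  for (nm in c("expression", "methylation")) {
    m <- if (nm == "expression") expression else methylation
    missing_meta <- setdiff(colnames(m), samples$sample_id)
    if (length(missing_meta)) {
      abort(sprintf("Sample column(s) missing from metadata: %s",
                    paste(missing_meta, collapse = ", ")))
    }
  }
  if (!setequal(colnames(expression), colnames(methylation))) {
    abort("Expression and methylation matrices must share the same samples.")
  }
  samples <- samples |> filter(.data$sample_id %in% colnames(expression))
  pair_check <- samples |>
    group_by(.data$subject_id) |>
    summarise(n_ctrl = sum(.data$condition == "control"),
              n_irr = sum(.data$condition == "irradiated"), .groups = "drop")
  bad <- pair_check |> filter(.data$n_ctrl != 1 | .data$n_irr != 1)
  if (nrow(bad)) {
    abort(sprintf("Unpaired subject(s): %s",
                  paste(bad$subject_id, collapse = ", ")))
  }
  if (any(methylation < 0 | methylation > 1)) {
    abort("Beta values outside [0, 1] found in methylation matrix.")
  }
  methylation <- pmin(pmax(methylation, beta_clamp), 1 - beta_clamp)
  if (any(expression < 0)) abort("TPM values must be non-negative.")

  ord <- samples$sample_id
  structure(
    list(expression = expression[, ord, drop = FALSE],
         methylation_beta = methylation[, ord, drop = FALSE],
         samples = samples,
         subjects = subjects |> filter(.data$subject_id %in% samples$subject_id)),
    class = "photomics_cohort"
  )
}

#' Read a GMT gene-set file
#'
#' MSigDB dialect: one set per line, tab-separated — set name, description,
#' then one or more gene ids.
#'
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      abort(sprintf("Malformed GMT line %d: expected name, description and >=1 gene.", i))
    }
    sets[[parts[1]]] <- parts[-(1:2)]
  }
  sets
}

#' Write a GMT gene-set file
#' @param gene_sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(gene_sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(gene_sets))
  lines <- vapply(seq_along(gene_sets), function(i) {
    paste(c(names(gene_sets)[i], descriptions[i], gene_sets[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED4+ block table
#'
#' Columns: chromosome, start, end (0-based half-open) and an optional fourth
#' column holding the reference methylation delta of the block.
#'
#' @param path BED file path.
#' @return Tibble with `chromosome`, `start`, `end`, `reference_delta`
#'   (NA when the file has only 3 columns) and a generated `block_id`.
#' @export
read_bed <- function(path) {
  df <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                        progress = FALSE)
  if (ncol(df) < 3) abort("BED file must have at least 3 columns.")
  out <- tibble(
    block_id = sprintf("block_%03d", seq_len(nrow(df))),
    chromosome = as.character(df[[1]]),
    start = as.integer(df[[2]]),
    end = as.integer(df[[3]]),
    reference_delta = if (ncol(df) >= 4) as.numeric(df[[4]]) else NA_real_
  )
  if (any(out$start >= out$end)) {
    abort("BED intervals must satisfy start < end (0-based half-open).")
  }
  out
}

#' Write a block table as BED4
#' @param blocks Tibble with chromosome, start, end, reference_delta.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(blocks, path) {
  readr::write_tsv(blocks[, c("chromosome", "start", "end", "reference_delta")],
                   path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Write the CpG manifest as TSV
#' @param manifest Manifest tibble as produced by [generate_annotations()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(manifest, path) {
  readr::write_tsv(manifest, path, progress = FALSE)
  invisible(path)
}

#' Read and validate a CpG manifest
#'
#' @param path Manifest TSV with columns cpg_id, chromosome, position
#'   (1-based), island_relation and gene_links (`"GENE:CLASS;..."`, possibly
#'   empty).
#' @return Validated manifest tibble.
#' @export
read_manifest <- function(path) {
  m <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(gene_links = readr::col_character()))
  m$gene_links[is.na(m$gene_links)] <- ""
  validate_manifest(m)
}

validate_manifest <- function(manifest) {
  dup <- manifest$cpg_id[duplicated(manifest$cpg_id)]
  if (length(dup)) {
    abort(sprintf("Duplicated cpg_id in manifest: %s",
                  paste(unique(dup), collapse = ", ")))
  }
  if (any(manifest$position < 1)) abort("Manifest positions must be >= 1 (1-based).")
  bad_rel <- setdiff(unique(manifest$island_relation), ISLAND_RELATIONS)
  if (length(bad_rel)) {
    abort(sprintf("Unknown island relation token(s): %s",
                  paste(bad_rel, collapse = ", ")))
  }
  links <- manifest_links(manifest)
  bad_cls <- setdiff(unique(links$region_class), REGION_CLASSES)
  if (length(bad_cls)) {
    abort(sprintf("Unknown region class token(s): %s",
                  paste(bad_cls, collapse = ", ")))
  }
  manifest
}

#' Expand manifest gene links to long form
#'
#' @param manifest Manifest tibble.
#' @return Tibble with one row per (cpg_id, gene_id) link and its
#'   `region_class`.
#' @export
manifest_links <- function(manifest) {
  has <- nzchar(manifest$gene_links)
  if (!any(has)) {
    return(tibble(cpg_id = character(), gene_id = character(),
                  region_class = character()))
  }
  parts <- strsplit(manifest$gene_links[has], ";", fixed = TRUE)
  cpg <- rep(manifest$cpg_id[has], lengths(parts))
  toks <- unlist(parts, use.names = FALSE)
  split2 <- strsplit(toks, ":", fixed = TRUE)
  tibble(
    cpg_id = cpg,
    gene_id = vapply(split2, `[`, character(1), 1),
    region_class = vapply(split2, `[`, character(1), 2)
  )
}

#' Load manifest, gene sets and reference blocks
#'
#' @param manifest_path Manifest TSV path.
#' @param gmt_path GMT path.
#' @param bed_path BED4+ path.
#' @param expressed_genes Optional character vector; genes in the GMT absent
#'   from it are retained but flagged in the `unmatched_genes` attribute of
#'   the returned gene-set list.
#' @return List with `manifest`, `gene_sets`, `blocks`.
#' @export
load_annotations <- function(manifest_path, gmt_path, bed_path,
                             expressed_genes = NULL) {
  manifest <- read_manifest(manifest_path)
  gene_sets <- read_gmt(gmt_path)
  if (!is.null(expressed_genes)) {
    unmatched <- lapply(gene_sets, function(g) setdiff(g, expressed_genes))
    n_un <- sum(lengths(unmatched))
    if (n_un > 0) {
      warn(sprintf("%d gene-set member(s) absent from the expression matrix (retained, flagged).",
                   n_un))
    }
    attr(gene_sets, "unmatched_genes") <- unmatched
  }
  blocks <- read_bed(bed_path)
  list(manifest = manifest, gene_sets = gene_sets, blocks = blocks)
}

#' Test CpG membership in genomic blocks
#'
#' Manifest positions are 1-based, block intervals 0-based half-open; a CpG at
#' 1-based position p belongs to a block `[start, end)` iff
#' `start < p <= end`.
#'
#' @param manifest Manifest tibble.
#' @param blocks Block tibble from [read_bed()] or [generate_annotations()].
#' @return Tibble with `cpg_id` and `block_id` for every membership.
#' @export
cpgs_in_blocks <- function(manifest, blocks) {
  out <- vector("list", nrow(blocks))
  for (i in seq_len(nrow(blocks))) {
    hit <- manifest$chromosome == blocks$chromosome[i] &
      manifest$position - 1L >= blocks$start[i] &
      manifest$position - 1L < blocks$end[i]
    if (any(hit)) {
      out[[i]] <- tibble(cpg_id = manifest$cpg_id[hit],
                         block_id = blocks$block_id[i])
    }
  }
  bind_rows(out)
}

#' Write a full synthetic dataset to disk
#'
#' Convenience wrapper writing cohort matrices, metadata, manifest, GMT, BED,
#' ground truth (JSON) and the configuration (YAML) into one directory.
#'
#' @param config A [cohort_config()].
#' @param dir Output directory.
#' @return Invisibly, a named list of paths.
#' @export
write_synthetic_dataset <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cc <- generate_cohort(config)
  ann <- generate_annotations(config)
  paths <- write_cohort(cc$cohort, dir)
  paths$manifest <- write_manifest(ann$manifest, file.path(dir, "manifest.tsv"))
  paths$gmt <- write_gmt(ann$gene_sets, file.path(dir, "gene_sets.gmt"))
  paths$bed <- write_bed(ann$blocks, file.path(dir, "blocks.bed"))
  paths$truth <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(lapply(unclass(cc$truth), as.data.frame),
                       paths$truth, digits = NA)
  paths$config <- file.path(dir, "config.yaml")
  yaml::write_yaml(unclass(config), paths$config)
  invisible(paths)
}
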