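# shared fixtures; the default cohort is expensive enough to cache per session
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- force(expr)
  }
  .fixture_cache[[key]]
}

default_cohort <- function() {
  cached("default_cohort", generate_cohort(cohort_config(seed = 1)))
}

default_annotations <- function() {
  cached("default_annotations", generate_annotations(cohort_config(seed = 1)))
}

default_differential <- function() {
  cached("default_differential", differential_cohort(default_cohort()$cohort))
}

tiny_config <- function(seed = 1, ...) {
  defaults <- list(
    n_subjects = 8, n_genes = 60, n_cpgs = 300,
    genes_per_subtype_pathway = 5, cpgs_per_subtype_gene = 2,
    n_med_predictive_features = 5, n_null_sets = 2, null_set_size = 10,
    shared_pathway_size = 8, n_blocks = 6, n_concordant_blocks = 3,
    seed = seed
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(cohort_config, args)
}
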