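# Small cohorts shared across tests: scaled-down feature space for speed,
# same latent structure as the defaults.
small_config <- function(...) {
  cohort_config(n_subjects = 60, n_genes = 400, n_cpgs = 400,
                n_informative_sets = 6, set_size = 10,
                clock_cpg_count = 40, ...)
}

small_cohort <- function(seed = 1, ...) {
  generate_cohort(small_config(seed = seed, ...))
}

truth_assignment <- function(cohort) {
  as_phase_assignment(cohort$truth, cohort$metadata)
}

# tiny omics matrix with explicit values
toy_matrix <- function(values, kind = "expression", scale = "log2_tpm",
                       features = NULL, subjects = NULL, ...) {
  m <- as.matrix(values)
  rownames(m) <- features %||% sprintf("f%02d", seq_len(nrow(m)))
  colnames(m) <- subjects %||% sprintf("s%02d", seq_len(ncol(m)))
  omics_matrix(m, kind = kind, scale = scale, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
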