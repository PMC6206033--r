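# Programmatic fixtures shared across test files.

# A small, fast cohort configuration; override any field via ...
tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(
    n_patients = 200, n_peptides = 80, n_housekeeping = 10,
    n_planted_per_stratum = 6, seed = 101
  )
  do.call(cohort_config, utils::modifyList(defaults, args))
}

# Build a peptide_matrix directly from a plain matrix.
make_matrix <- function(values, housekeeping = character(0),
                        sample_prefix = "s", peptide_prefix = "p") {
  if (is.null(rownames(values))) {
    rownames(values) <- paste0(sample_prefix, seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0(peptide_prefix, seq_len(ncol(values)))
  }
  peptide_matrix(values, housekeeping_ids = housekeeping)
}

# Two-group zero-inflated log-normal matrix with an optional planted shift,
# plus a matching labels table (single stratum). Used for discovery and
# classifier tests without running the full generator.
two_group_matrix <- function(n_case = 30, n_control = 50, n_peptides = 40,
                             planted = integer(0), log2_effect = 1,
                             detect_prob = 0.8, seed = 1) {
  set.seed(seed)
  n <- n_case + n_control
  amp <- matrix(0, n, n_peptides,
                dimnames = list(sprintf("s%03d", 1:n), sprintf("p%03d", 1:n_peptides)))
  is_case <- c(rep(TRUE, n_case), rep(FALSE, n_control))
  for (j in seq_len(n_peptides)) {
    delta <- if (j %in% planted) log2_effect * log(2) else 0
    det <- runif(n) < detect_prob
    amp[, j] <- ifelse(det, exp(rnorm(n, 4 + delta * is_case, 1)), 0)
  }
  labels <- data.frame(
    patient_id = rownames(amp),
    slope = ifelse(is_case, -6, 0),
    label = ifelse(is_case, "rapid", "stable"),
    stratum = 1L,
    stringsAsFactors = FALSE
  )
  list(matrix = make_matrix(amp), labels = labels, is_case = is_case)
}
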