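#' Construct a peptide amplitude matrix
#'
#' The feature container of the pipeline: a numeric samples x peptides
#' matrix of non-negative amplitudes in which 0 means "peptide not detected
#' in that sample", plus the ids of the housekeeping peptides used for
#' normalization.
#'
#' @param amplitudes numeric matrix with sample ids as rownames and peptide
#'   ids as colnames; non-negative, 0 = not detected
#' @param housekeeping_ids character subset of the peptide ids
#' @return an object of class `peptide_matrix`
#' @export
peptide_matrix <- function(amplitudes, housekeeping_ids = character(0)) {
  if (!is.matrix(amplitudes) || !is.numeric(amplitudes)) {
    stopf("amplitudes must be a numeric matrix")
  }
  if (is.null(rownames(amplitudes)) || is.null(colnames(amplitudes))) {
    stopf("amplitudes must have sample rownames and peptide colnames")
  }
  if (any(amplitudes < 0)) stopf("amplitudes must be non-negative")
  missing_hk <- setdiff(housekeeping_ids, colnames(amplitudes))
  if (length(missing_hk)) {
    stopf("housekeeping ids not in matrix: %s", paste(missing_hk, collapse = ", "))
  }
  structure(
    list(amplitudes = amplitudes, housekeeping_ids = housekeeping_ids),
    class = "peptide_matrix"
  )
}

#' @export
print.peptide_matrix <- function(x, ...) {
  cat(sprintf(
    "peptide_matrix: %d samples x %d peptides (%d housekeeping), %.1f%% detected\n",
    nrow(x$amplitudes), ncol(x$amplitudes), length(x$housekeeping_ids),
    100 * mean(x$amplitudes > 0)
  ))
  invisible(x)
}

#' Normalize a peptide matrix against its housekeeping peptides
#'
#' Corrects sample-to-sample analytical and urine-dilution variation by
#' dividing each sample's amplitudes by the mean amplitude of the
#' housekeeping peptides detected in that sample, then multiplying by a
#' common reference level. Zeros (non-detections) stay zero and
#' within-sample amplitude ratios are preserved exactly.
#'
#' The reference level sets the output scale only:
#' \describe{
#'   \item{`"unit"` (default)}{reference 1 — each sample's detected
#'     housekeeping mean becomes 1. Strictly invariant to per-sample
#'     rescaling and comparable across cohorts.}
#'   \item{`"grand_mean"`}{reference = mean over samples of the per-sample
#'     detected housekeeping means, which keeps the output on the input's
#'     amplitude scale but makes the overall level depend on cohort
#'     composition.}
#'   \item{a number}{any fixed positive reference.}
#' }
#' Either way the transformation is idempotent. The reference actually used
#' is recorded in the `normalization` attribute of the result.
#'
#' @param matrix a [peptide_matrix()] with non-empty housekeeping ids
#' @param reference `"unit"`, `"grand_mean"`, or a positive number
#' @return the normalized `peptide_matrix`
#' @export
normalize_matrix <- function(matrix, reference = "unit") {
  if (!inherits(matrix, "peptide_matrix")) stopf("expected a peptide_matrix")
  hk <- matrix$housekeeping_ids
  if (!length(hk)) stopf("normalization requires housekeeping peptides")
  amp <- matrix$amplitudes
  hk_amp <- amp[, hk, drop = FALSE]
  sample_means <- apply(hk_amp, 1, function(v) {
    d <- v[v > 0]
    if (!length(d)) NA_real_ else mean(d)
  })
  bad <- names(sample_means)[is.na(sample_means)]
  if (length(bad)) {
    stopf(
      "samples with no detected housekeeping peptide: %s",
      paste(bad, collapse = ", ")
    )
  }
  ref <- if (identical(reference, "unit")) {
    1
  } else if (identical(reference, "grand_mean")) {
    mean(sample_means)
  } else if (is.numeric(reference) && length(reference) == 1 && reference > 0) {
    as.numeric(reference)
  } else {
    stopf("reference must be \"unit\", \"grand_mean\", or a positive number")
  }
  out <- amp * (ref / sample_means)  # recycles per row
  res <- peptide_matrix(out, housekeeping_ids = hk)
  attr(res, "normalization") <- list(reference = reference, reference_value = ref)
  res
}

#' Per-peptide descriptive statistics between cases and controls
#'
#' Amplitude means are computed over detected (non-zero) samples only, since
#' zero encodes non-detection rather than true zero abundance; the detection
#' information is carried separately by the group frequencies. The mean
#' relative abundance is mean amplitude times detection frequency, and the
#' fold change is the case mean divided by the control mean (flagged
#' undefined, not infinite, when the peptide is never detected in controls).
#'
#' @param matrix a [peptide_matrix()]
#' @param case_ids,control_ids disjoint, non-empty sample id sets
#' @param peptide_id a single peptide id present in the matrix
#' @return list with fields `peptide_id`, `mean_amplitude_cases`,
#'   `mean_amplitude_controls`, `frequency_cases`, `frequency_controls`,
#'   `mean_relative_abundance_cases`, `mean_relative_abundance_controls`,
#'   `fold_change`, `fold_change_defined`
#' @export
peptide_summary <- function(matrix, case_ids, control_ids, peptide_id) {
  if (!inherits(matrix, "peptide_matrix")) stopf("expected a peptide_matrix")
  amp <- matrix$amplitudes
  if (!peptide_id %in% colnames(amp)) stopf("peptide %s absent from matrix", peptide_id)
  if (!length(case_ids) || !length(control_ids)) stopf("both groups must be non-empty")
  if (length(intersect(case_ids, control_ids))) stopf("case and control ids overlap")
  missing <- setdiff(c(case_ids, control_ids), rownames(amp))
  if (length(missing)) stopf("sample ids absent from matrix: %s", paste(missing, collapse = ", "))

  grp <- function(ids) {
    v <- amp[ids, peptide_id]
    d <- v[v > 0]
    list(
      mean = if (length(d)) mean(d) else 0,
      freq = length(d) / length(ids)
    )
  }
  ca <- grp(case_ids)
  co <- grp(control_ids)
  defined <- co$mean > 0
  list(
    peptide_id = peptide_id,
    mean_amplitude_cases = ca$mean,
    mean_amplitude_controls = co$mean,
    frequency_cases = ca$freq,
    frequency_controls = co$freq,
    mean_relative_abundance_cases = ca$mean * ca$freq,
    mean_relative_abundance_controls = co$mean * co$freq,
    fold_change = if (defined) ca$mean / co$mean else NA_real_,
    fold_change_defined = defined
  )
}
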