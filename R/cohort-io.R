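# Plain-text serialization of cohorts: TSV peptide matrix (first column the
# sample id, header row of peptide ids), CSV clinical and trajectory tables,
# JSON ground truth.

#' Write a peptide matrix as TSV
#'
#' First column `sample_id`, remaining columns one per peptide. Housekeeping
#' ids are recorded in a `# housekeeping:` comment on the first line.
#'
#' @param matrix a [peptide_matrix()]
#' @param path output file
#' @export
write_peptide_matrix <- function(matrix, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# housekeeping: %s",
                     paste(matrix$housekeeping_ids, collapse = ",")), con)
  df <- data.frame(sample_id = rownames(matrix$amplitudes),
                   matrix$amplitudes, check.names = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a peptide matrix written by [write_peptide_matrix()]
#'
#' @param path TSV file path
#' @return a [peptide_matrix()]
#' @export
read_peptide_matrix <- function(path) {
  first <- readLines(path, n = 1)
  hk <- character(0)
  skip <- 0
  if (startsWith(first, "# housekeeping:")) {
    ids <- trimws(sub("^# housekeeping:", "", first))
    if (nzchar(ids)) hk <- strsplit(ids, ",")[[1]]
    skip <- 1
  }
  df <- read.delim(path, skip = skip, check.names = FALSE,
                   stringsAsFactors = FALSE)
  amp <- as.matrix(df[, -1, drop = FALSE])
  rownames(amp) <- df[[1]]
  peptide_matrix(amp, housekeeping_ids = hk)
}

#' Write a generated cohort to a directory of plain-text files
#'
#' Produces `matrix.tsv`, `clinical.csv`, `trajectories.csv` and
#' `ground_truth.json`.
#'
#' @param cohort result of [generate_cohort()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_peptide_matrix(cohort$matrix, file.path(dir, "matrix.tsv"))
  write.csv(cohort$clinical, file.path(dir, "clinical.csv"), row.names = FALSE)
  write.csv(cohort$trajectories, file.path(dir, "trajectories.csv"),
            row.names = FALSE)
  jsonlite::write_json(cohort$truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir directory path
#' @return list(matrix, clinical, trajectories, truth); `truth` is NULL when
#'   no ground-truth file is present (real data).
#' @export
read_cohort <- function(dir) {
  truth_path <- file.path(dir, "ground_truth.json")
  list(
    matrix = read_peptide_matrix(file.path(dir, "matrix.tsv")),
    clinical = read.csv(file.path(dir, "clinical.csv"),
                        stringsAsFactors = FALSE),
    trajectories = read.csv(file.path(dir, "trajectories.csv"),
                            stringsAsFactors = FALSE),
    truth = if (file.exists(truth_path)) {
      jsonlite::read_json(truth_path, simplifyVector = TRUE)
    }
  )
}
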