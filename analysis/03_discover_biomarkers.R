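#!/usr/bin/env Rscript
# Normalize the peptide matrix against the housekeeping peptides and run
# per-stratum differential discovery (Wilcoxon rank-sum on normalized
# amplitudes with zeros as lowest ties, Benjamini-Hochberg across peptides,
# detection frequency > 30% in at least one group).
#
# Reads results/cohort/ and results/labels.csv; writes
# results/discovery/stratum_<s>.csv and results/discovery/top10_stratum_<s>.csv.

suppressPackageStartupMessages(library(ckdstrata))

cohort <- read_cohort("results/cohort")
labels <- read.csv("results/labels.csv", stringsAsFactors = FALSE)
norm <- normalize_matrix(cohort$matrix)
dir.create("results/discovery", recursive = TRUE, showWarnings = FALSE)

lab_cc <- labels[labels$label %in% c("rapid", "stable"), ]
counts <- table(factor(lab_cc$stratum, levels = 1:7), lab_cc$label)

for (s in 1:7) {
  if (counts[s, "rapid"] < 2 || counts[s, "stable"] < 2) {
    cat(sprintf("stratum %d: skipped (too few cases or controls)\n", s))
    next
  }
  d <- discover_stratum(norm, labels, s)
  write.csv(d$table, sprintf("results/discovery/stratum_%d.csv", s),
            row.names = FALSE)
  top <- top_differential(d, k = 10)
  write.csv(top, sprintf("results/discovery/top10_stratum_%d.csv", s),
            row.names = FALSE)
  planted <- cohort$truth$planted_ids[[paste0("stratum_", s)]]
  sel <- d$table$peptide_id[d$table$selected]
  cat(sprintf(
    "stratum %d: %3d cases / %3d controls -> %2d selected (planted recovered %d/%d)\n",
    s, d$n_cases, d$n_controls, length(sel),
    length(intersect(sel, planted)), length(planted)
  ))
}
cat("Wrote results/discovery/\n")
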