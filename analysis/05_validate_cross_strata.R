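#!/usr/bin/env Rscript
# Cross-stratum validation: every stratum-trained subclassifier is
# evaluated in every other stratum; for each validation stratum the best
# externally trained subclassifier is reported next to the comparators
# (albuminuria as a direct score, a base-panel-only model trained on the
# other strata, and 2-/5-year KFRE risk).
#
# Reads results/cohort/ and results/labels.csv; writes
# results/validation/{auc_grid.csv,best_subclassifiers.csv,comparators.csv}.

suppressPackageStartupMessages(library(ckdstrata))

seed <- 20260925L
cohort <- read_cohort("results/cohort")
labels <- read.csv("results/labels.csv", stringsAsFactors = FALSE)
norm <- normalize_matrix(cohort$matrix)
dir.create("results/validation", recursive = TRUE, showWarnings = FALSE)

set.seed(seed)
base_panel <- sort(sample(
  setdiff(colnames(norm$amplitudes),
          c(norm$housekeeping_ids, unique(unlist(cohort$truth$planted_ids)))),
  20
))

vg <- cross_stratum_run(norm, cohort$clinical, labels, base_panel,
                        cv_folds = 3, seed = seed)
write.csv(vg$grid, "results/validation/auc_grid.csv", row.names = FALSE)
write.csv(vg$best, "results/validation/best_subclassifiers.csv", row.names = FALSE)
write.csv(vg$comparators, "results/validation/comparators.csv", row.names = FALSE)

cat("Best externally trained subclassifier per validation stratum:\n")
print(vg$best, row.names = FALSE)
cat("\nComparator AUCs per validation stratum:\n")
print(vg$comparators, row.names = FALSE, digits = 3)
cat("\nWrote results/validation/\n")
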