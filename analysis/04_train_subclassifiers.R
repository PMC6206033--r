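#!/usr/bin/env Rscript
# Train one SVM subclassifier per eligible stratum: candidate panel =
# stand-in base panel + stratum discoveries; RBF C-classification SVM
# tuned by cross-validated AUC. For the largest stratum the panel is also
# pruned by take-one-out backward elimination to show the reduction step.
#
# Reads results/cohort/, results/labels.csv, results/discovery/;
# writes results/models/stratum_<s>.json.

suppressPackageStartupMessages(library(ckdstrata))

seed <- 20260925L
cohort <- read_cohort("results/cohort")
labels <- read.csv("results/labels.csv", stringsAsFactors = FALSE)
norm <- normalize_matrix(cohort$matrix)
dir.create("results/models", recursive = TRUE, showWarnings = FALSE)

# stand-in base panel: 20 background peptides chosen reproducibly
set.seed(seed)
base_panel <- sort(sample(
  setdiff(colnames(norm$amplitudes),
          c(norm$housekeeping_ids, unique(unlist(cohort$truth$planted_ids)))),
  20
))

lab_cc <- labels[labels$label %in% c("rapid", "stable"), ]
counts <- table(factor(lab_cc$stratum, levels = 1:7), lab_cc$label)

for (s in 1:7) {
  disc_path <- sprintf("results/discovery/stratum_%d.csv", s)
  if (!file.exists(disc_path) || counts[s, "rapid"] < 2 || counts[s, "stable"] < 2) next
  tab <- read.csv(disc_path, stringsAsFactors = FALSE)
  disc <- structure(list(stratum = s, table = tab), class = "discovery_result")
  panel <- build_candidate_panel(disc, base_panel)
  lab_s <- labels[labels$stratum == s, ]
  model <- if (s == 1 && nrow(panel) > 10) {
    take_one_out_reduce(norm, lab_s, panel, cv_folds = 3, seed = seed,
                        min_panel = 10, stratum = s)
  } else {
    train_svm(norm, lab_s, panel, cv_folds = 3, seed = seed, stratum = s)
  }
  save_model(model, sprintf("results/models/stratum_%d.json", s))
  cat(sprintf("stratum %d: panel %d -> %d peptides, CV AUC %.3f\n",
              s, nrow(panel), length(model$panel), model$metadata$cv_auc))
}
cat("Wrote results/models/\n")
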