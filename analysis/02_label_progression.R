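#!/usr/bin/env Rscript
# Estimate per-patient eGFR slopes by least squares, label progression
# (rapid <= -5; stable in [-1.5, +5]; grey zone and rising excluded), and
# assign baseline-eGFR strata.
#
# Reads results/cohort/; writes results/labels.csv.

suppressPackageStartupMessages(library(ckdstrata))

cohort <- read_cohort("results/cohort")
labels <- label_cohort(cohort$clinical, cohort$trajectories)
write.csv(labels, "results/labels.csv", row.names = FALSE)

cat("Progression labels:\n")
print(table(labels$label))
cat(sprintf("\nExcluded (grey zone + rising): %d of %d\n",
            sum(grepl("^excluded", labels$label)), nrow(labels)))
cat("\nCase/control counts per stratum (included patients):\n")
lab_cc <- labels[labels$label %in% c("rapid", "stable"), ]
print(table(stratum = lab_cc$stratum, label = lab_cc$label))

# how well do noisy-slope labels agree with the generator's truth?
agree <- mean(lab_cc$label ==
                ifelse(cohort$clinical$true_group[match(lab_cc$patient_id,
                                                        cohort$clinical$patient_id)] == "rapid",
                       "rapid", "stable"))
cat(sprintf("\nLabel agreement with ground truth among included patients: %.1f%%\n",
            100 * agree))
cat("Wrote results/labels.csv\n")
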