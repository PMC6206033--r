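#!/usr/bin/env Rscript
# Simulate the study cohort: 1482 patients distributed over 7 baseline-eGFR
# strata with stratum-specific rapid-progressor fractions, covariate shifts
# between outcome groups, longitudinal eGFR trajectories, and a peptide
# matrix with 29 housekeeping peptides and 15 planted differential peptides
# per stratum (adjacent strata share half of them).
#
# Writes results/cohort/{matrix.tsv,clinical.csv,trajectories.csv,
# ground_truth.json}.

suppressPackageStartupMessages(library(ckdstrata))

seed <- 20260925L
cfg <- cohort_config(
  n_patients = 1482, n_peptides = 300, n_housekeeping = 29,
  n_planted_per_stratum = 15, planted_log2_effect = 1.0,
  planted_overlap = 0.5, seed = seed
)
cohort <- generate_cohort(cfg)
write_cohort(cohort, "results/cohort")

cl <- cohort$clinical
cat(sprintf("Simulated %d patients (%d peptides, %d housekeeping)\n",
            nrow(cl), cfg$n_peptides, cfg$n_housekeeping))
cat("\nGround-truth outcome group by stratum:\n")
print(table(group = cl$true_group, stratum = cl$true_stratum))

by_group <- split(cl, cl$true_group)
cat("\nCovariate shifts between outcome groups (cf. the emulated cohort):\n")
for (g in names(by_group)) {
  b <- by_group[[g]]
  cat(sprintf(
    "  %-6s n=%4d  diabetes %.1f%%  age %.1f  SBP %.1f  UAE %.0f mg/24h  follow-up %.2f y\n",
    g, nrow(b), 100 * mean(b$diabetes), mean(b$age), mean(b$sbp),
    mean(b$uae), mean(b$followup_years)
  ))
}
cat("\nWrote results/cohort/\n")
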