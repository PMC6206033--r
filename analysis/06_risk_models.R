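#!/usr/bin/env Rscript
# Clinical comparator models: 4-variable KFRE risk at 2 and 5 years per
# patient, and Cox proportional-hazards association of the best validated
# subclassifier score with rapid progression, adjusted for albuminuria,
# diabetes and baseline eGFR.
#
# Reads results/cohort/, results/labels.csv, results/models/,
# results/validation/; writes results/kfre.csv and results/cox.json.

suppressPackageStartupMessages(library(ckdstrata))

cohort <- read_cohort("results/cohort")
labels <- read.csv("results/labels.csv", stringsAsFactors = FALSE)
norm <- normalize_matrix(cohort$matrix)
best <- read.csv("results/validation/best_subclassifiers.csv",
                 stringsAsFactors = FALSE)

cl <- cohort$clinical
kfre <- kfre_risk(cl$age, cl$sex, cl$baseline_egfr, cl$acr)
write.csv(cbind(patient_id = cl$patient_id, kfre), "results/kfre.csv",
          row.names = FALSE)
cat(sprintf("KFRE: mean 2-yr risk %.2f%%, mean 5-yr risk %.2f%% (n = %d)\n",
            100 * mean(kfre$risk_2yr), 100 * mean(kfre$risk_5yr), nrow(cl)))

# score each included patient with the subclassifier validated best for
# their stratum
lab_cc <- labels[labels$label %in% c("rapid", "stable"), ]
cli <- cl[match(lab_cc$patient_id, cl$patient_id), ]
scores <- rep(NA_real_, nrow(lab_cc))
for (s in unique(lab_cc$stratum)) {
  b <- best[best$val_stratum == s, ]
  train_s <- if (nrow(b)) b$best_train_stratum else s
  path <- sprintf("results/models/stratum_%d.json", train_s)
  if (!file.exists(path)) path <- sprintf("results/models/stratum_%d.json", s)
  if (!file.exists(path)) next
  model <- load_model(path)
  in_s <- lab_cc$stratum == s
  scores[in_s] <- score(model, norm, sample_ids = lab_cc$patient_id[in_s])
}
keep <- !is.na(scores)
fit <- cox_association(
  scores[keep], cli$followup_years[keep], lab_cc$label[keep] == "rapid",
  covariates = data.frame(log_uae = log1p(cli$uae[keep]),
                          diabetes = cli$diabetes[keep],
                          baseline_egfr = cli$baseline_egfr[keep])
)
jsonlite::write_json(fit[c("hazard_ratio", "ci_low", "ci_high", "p_value",
                           "scale", "n_events")],
                     "results/cox.json", auto_unbox = TRUE, digits = NA)
cat(sprintf(
  "Cox (adjusted): HR %s = %.2f (95%% CI %.2f-%.2f), p = %.3g, %d events\n",
  fit$scale, fit$hazard_ratio, fit$ci_low, fit$ci_high, fit$p_value,
  fit$n_events
))
cat("Wrote results/kfre.csv and results/cox.json\n")
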