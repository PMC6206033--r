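#' Run the full stratified-classifier study end to end
#'
#' Executes the complete workflow on a synthetic cohort (or on matrix +
#' clinical tables read from disk): housekeeping normalization, eGFR-slope
#' labeling and stratification, per-stratum discovery, subclassifier
#' training, cross-stratum validation with comparators (albuminuria,
#' base-panel model, KFRE), and the Cox association of the best
#' subclassifier scores with rapid progression. Returns a structured
#' report; every parameter and derived seed is logged in the report so any
#' stage can be reproduced in isolation.
#'
#' @param config list with elements
#'   \describe{
#'     \item{cohort}{a [cohort_config()] for synthesis, OR}
#'     \item{input_dir}{directory with files written by [write_cohort()]}
#'     \item{base_panel_size}{stand-in base panel: this many non-planted
#'       peptide ids chosen reproducibly (default 20)}
#'     \item{alpha, min_freq}{discovery parameters (defaults 0.05, 0.3)}
#'     \item{reduce, cv_folds, min_panel, tolerance}{classifier parameters}
#'     \item{min_cases}{underpowered-stratum flag threshold (default 10)}
#'     \item{seed}{mandatory master seed}
#'   }
#' @param outdir optional directory; when given, the report is written as
#'   `report.json` and `report.md` plus CSV tables
#' @return the report (list), invisibly containing the fitted
#'   `validation_grid`
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.null(config$seed)) stopf("config$seed is mandatory")
  seed <- as.integer(config$seed)
  has_cohort <- !is.null(config$cohort)
  has_input <- !is.null(config$input_dir)
  if (!has_cohort && !has_input) stopf("config needs either `cohort` or `input_dir`")

  cohort <- if (has_cohort) generate_cohort(config$cohort) else read_cohort(config$input_dir)

  norm <- normalize_matrix(cohort$matrix)
  labels <- label_cohort(cohort$clinical, cohort$trajectories)

  # stand-in base panel: reproducibly chosen non-housekeeping, non-planted ids
  n_base <- config$base_panel_size %||% 20
  pool <- setdiff(colnames(norm$amplitudes), norm$housekeeping_ids)
  if (!is.null(cohort$truth)) {
    pool <- setdiff(pool, unique(unlist(cohort$truth$planted_ids)))
  }
  base_panel <- with_seed(substream_seed(seed, "base_panel"),
                          sort(sample(pool, min(n_base, length(pool)))))

  vg <- cross_stratum_run(
    norm, cohort$clinical, labels, base_panel,
    alpha = config$alpha %||% 0.05,
    min_freq = config$min_freq %||% 0.3,
    reduce = isTRUE(config$reduce),
    cv_folds = config$cv_folds %||% 5,
    seed = substream_seed(seed, "classifier"),
    min_panel = config$min_panel %||% 5,
    tolerance = config$tolerance %||% 0.002,
    min_cases = config$min_cases %||% 10
  )

  # Cox association: score every labeled patient with the subclassifier that
  # validated best for their stratum (falling back to any model for strata
  # without an external best), adjusted for albuminuria, diabetes and
  # baseline eGFR
  lab_cc <- labels[labels$label %in% c("rapid", "stable"), ]
  cl <- cohort$clinical[match(lab_cc$patient_id, cohort$clinical$patient_id), ]
  sc <- rep(NA_real_, nrow(lab_cc))
  for (s in unique(lab_cc$stratum)) {
    b <- vg$best[vg$best$val_stratum == s, ]
    model_id <- if (nrow(b)) as.character(b$best_train_stratum) else names(vg$models)[1]
    if (!model_id %in% names(vg$models)) model_id <- names(vg$models)[1]
    in_s <- lab_cc$stratum == s
    sc[in_s] <- score(vg$models[[model_id]]$model, norm,
                      sample_ids = lab_cc$patient_id[in_s])
  }
  cox <- cox_association(
    scores = sc,
    followup_years = cl$followup_years,
    event = lab_cc$label == "rapid",
    covariates = data.frame(log_uae = log1p(cl$uae), diabetes = cl$diabetes,
                            baseline_egfr = cl$baseline_egfr)
  )

  label_counts <- table(factor(labels$label, levels = c(
    "rapid", "stable", "excluded_grey_zone", "excluded_rising"
  )))
  stratum_counts <- as.data.frame(table(
    stratum = factor(lab_cc$stratum, levels = 1:7),
    label = lab_cc$label
  ))

  top10 <- lapply(vg$models, function(m) {
    top_differential(m$discovery, k = 10, base_panel = base_panel)
  })

  report <- list(
    parameters = list(
      seed = seed,
      alpha = config$alpha %||% 0.05, min_freq = config$min_freq %||% 0.3,
      reduce = isTRUE(config$reduce), cv_folds = config$cv_folds %||% 5,
      min_panel = config$min_panel %||% 5,
      tolerance = config$tolerance %||% 0.002,
      base_panel = base_panel,
      classifier_seed = substream_seed(seed, "classifier"),
      synthetic = has_cohort
    ),
    cohort_summary = cohort_summary(cohort$clinical),
    label_counts = as.list(label_counts),
    n_excluded = sum(label_counts[c("excluded_grey_zone", "excluded_rising")]),
    stratum_counts = stratum_counts,
    panel_sizes = vapply(vg$models, function(m) length(m$model$panel), integer(1)),
    auc_grid = vg$grid,
    best_subclassifiers = vg$best,
    comparators = vg$comparators,
    top_differential = top10,
    cox = cox[c("hazard_ratio", "ci_low", "ci_high", "p_value", "scale", "n_events")]
  )

  if (!is.null(outdir)) write_report(report, outdir)
  report$validation <- vg
  invisible(report)
}

# Table-1-style cohort description by ground-truth or labeled group.
cohort_summary <- function(clinical) {
  num <- function(v) c(mean = mean(v), sd = sd(v))
  list(
    n = nrow(clinical),
    age = num(clinical$age),
    female_pct = 100 * mean(clinical$sex == "female"),
    diabetes_pct = 100 * mean(clinical$diabetes),
    sbp = num(clinical$sbp),
    uae = num(clinical$uae),
    baseline_egfr = num(clinical$baseline_egfr),
    followup_years = num(clinical$followup_years)
  )
}

write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    report[setdiff(names(report), "validation")],
    file.path(outdir, "report.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows", pretty = TRUE
  )
  write.csv(report$auc_grid, file.path(outdir, "auc_grid.csv"), row.names = FALSE)
  write.csv(report$best_subclassifiers, file.path(outdir, "best_subclassifiers.csv"),
            row.names = FALSE)
  write.csv(report$comparators, file.path(outdir, "comparators.csv"),
            row.names = FALSE)

  md <- c(
    "# Stratified subclassifier run report",
    "",
    sprintf("- Cohort: n = %d (synthetic: %s)", report$cohort_summary$n,
            report$parameters$synthetic),
    sprintf("- Labels: %s", paste(sprintf("%s = %d", names(report$label_counts),
                                          unlist(report$label_counts)),
                                  collapse = ", ")),
    sprintf("- Excluded (grey zone + rising): %d", report$n_excluded),
    sprintf("- Panel sizes: %s", paste(sprintf("stratum %s: %d",
                                               names(report$panel_sizes),
                                               report$panel_sizes),
                                       collapse = ", ")),
    sprintf("- Cox HR %s: %.3f (95%% CI %.3f-%.3f, p = %.3g, %d events)",
            report$cox$scale, report$cox$hazard_ratio, report$cox$ci_low,
            report$cox$ci_high, report$cox$p_value, report$cox$n_events),
    "",
    "## Best subclassifier per validation stratum",
    "",
    paste(utils::capture.output(print(report$best_subclassifiers, row.names = FALSE)),
          collapse = "\n")
  )
  writeLines(md, file.path(outdir, "report.md"))
  invisible(outdir)
}
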