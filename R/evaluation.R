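#' ROC analysis with DeLong confidence interval
#'
#' AUC by the pairwise-concordance/trapezoidal identity (ties counted 1/2)
#' with a 95\% confidence interval from DeLong's variance estimator (normal
#' interval clipped to [0, 1]), plus the full sensitivity/specificity curve.
#'
#' @param scores numeric classifier scores, higher = more case-like
#' @param labels logical (TRUE = case) or character ("rapid" = case) vector
#' @return object of class `roc_result`: list(auc, ci_low, ci_high,
#'   n_cases, n_controls, curve)
#' @export
roc_auc <- function(scores, labels) {
  is_case <- as_case(labels)
  if (!any(is_case) || all(is_case)) stopf("both classes must be present")
  r <- pROC::roc(response = factor(ifelse(is_case, "case", "control"),
                                   levels = c("control", "case")),
                 predictor = as.numeric(scores),
                 levels = c("control", "case"), direction = "<",
                 quiet = TRUE)
  ci <- suppressWarnings(as.numeric(pROC::ci.auc(r, method = "delong")))
  structure(list(
    auc = as.numeric(pROC::auc(r)),
    ci_low = max(0, ci[1]), ci_high = min(1, ci[3]),
    n_cases = sum(is_case), n_controls = sum(!is_case),
    curve = data.frame(threshold = r$thresholds,
                       sensitivity = r$sensitivities,
                       specificity = r$specificities)
  ), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f), %d cases / %d controls\n",
              x$auc, x$ci_low, x$ci_high, x$n_cases, x$n_controls))
  invisible(x)
}

as_case <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) return(labels != 0)
  labels <- as.character(labels)
  labels %in% c("case", "rapid", "TRUE", "1")
}

#' Compare two AUCs with the DeLong test
#'
#' Paired mode (same samples scored twice) uses DeLong's test for correlated
#' ROC curves; unpaired mode a normal test on independent DeLong variance
#' estimates. Two-sided p-value.
#'
#' @param scores_a,scores_b score vectors
#' @param labels outcome labels for `scores_a` (and for `scores_b` when
#'   paired)
#' @param labels_b outcome labels for `scores_b` in unpaired mode (defaults
#'   to `labels`)
#' @param paired logical
#' @return list(auc_a, auc_b, auc_difference, p_value)
#' @export
compare_auc <- function(scores_a, scores_b, labels, paired = TRUE,
                        labels_b = labels) {
  mk_roc <- function(s, l) {
    is_case <- as_case(l)
    pROC::roc(response = factor(ifelse(is_case, "case", "control"),
                                levels = c("control", "case")),
              predictor = as.numeric(s),
              levels = c("control", "case"), direction = "<", quiet = TRUE)
  }
  if (paired && length(scores_a) != length(scores_b)) {
    stopf("paired comparison requires equal-length score vectors")
  }
  ra <- mk_roc(scores_a, labels)
  rb <- mk_roc(scores_b, labels_b)
  auc_a <- as.numeric(pROC::auc(ra))
  auc_b <- as.numeric(pROC::auc(rb))
  if (auc_a == auc_b) {
    # identical AUCs: difference 0; DeLong statistic is 0/0 when the scores
    # are rank-identical, so report p = 1 directly
    p <- 1
  } else {
    tst <- suppressWarnings(
      pROC::roc.test(ra, rb, method = "delong", paired = paired)
    )
    p <- as.numeric(tst$p.value)
    if (!is.finite(p)) p <- 1
  }
  list(auc_a = auc_a, auc_b = auc_b,
       auc_difference = auc_a - auc_b, p_value = p)
}

#' Operating point by the Youden index
#'
#' Scans all candidate thresholds (midpoints between adjacent distinct
#' scores, plus outer sentinels; predict case when score >= threshold) and
#' returns the one maximizing sensitivity + specificity - 1. Ties go to the
#' lowest threshold (highest sensitivity). PPV/NPV are flagged NA when
#' their denominator is empty, and the result is flagged degenerate when
#' the best Youden index is 0 (scores carry no information).
#'
#' @param scores numeric scores, higher = more case-like
#' @param labels case/control labels (see [roc_auc()])
#' @return list(threshold, sensitivity, specificity, ppv, npv, youden,
#'   degenerate)
#' @export
operating_point <- function(scores, labels) {
  is_case <- as_case(labels)
  if (!any(is_case) || all(is_case)) stopf("both classes must be present")
  s <- sort(unique(as.numeric(scores)))
  cand <- c(s[1] - 1, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2, s[length(s)] + 1)
  best <- NULL
  for (thr in cand) {
    pred <- scores >= thr
    tp <- sum(pred & is_case); fn <- sum(!pred & is_case)
    tn <- sum(!pred & !is_case); fp <- sum(pred & !is_case)
    sens <- tp / (tp + fn)
    spec <- tn / (tn + fp)
    j <- sens + spec - 1
    if (is.null(best) || j > best$youden + 1e-12) {
      best <- list(threshold = thr, sensitivity = sens, specificity = spec,
                   ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
                   npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
                   youden = j)
    }
  }
  best$degenerate <- best$youden <= 1e-12
  best
}

#' Cross-stratum training and validation of subclassifiers
#'
#' For every eligible training stratum: run differential discovery, combine
#' the selected peptides with the base panel, train a subclassifier
#' (optionally with take-one-out reduction), then evaluate it on its own
#' stratum (training-set performance, the grid diagonal) and on every other
#' stratum (independent validation, since strata partition the cohort by
#' baseline eGFR). For each validation stratum the best-performing
#' subclassifier is the one trained elsewhere with maximal validation AUC
#' (ties prefer the adjacent training stratum, then the lower stratum id).
#' Comparator AUCs per stratum: urinary albumin excretion used directly as
#' a score, a base-panel-only SVM trained on all other strata, and 2- and
#' 5-year kidney-failure risk from the 4-variable KFRE.
#'
#' Strata missing a class are skipped with a warning; strata with fewer
#' cases than `min_cases` are evaluated but flagged underpowered.
#'
#' @param matrix normalized [peptide_matrix()]
#' @param clinical clinical table (needs uae, acr, age, sex, baseline_egfr)
#' @param labels labeling table from [label_cohort()]
#' @param base_panel character vector of base-panel peptide ids
#' @param alpha,min_freq discovery parameters
#' @param reduce apply take-one-out reduction (default FALSE; the full
#'   candidate panel is used when off)
#' @param cv_folds,seed,min_panel,tolerance classifier parameters
#' @param min_cases underpowered-stratum threshold (default 10)
#' @return object of class `validation_grid`: list(grid, best, comparators,
#'   models, skipped). `grid` has one row per (train, validation) stratum
#'   pair with auc, ci and class counts; `best` one row per validation
#'   stratum.
#' @export
cross_stratum_run <- function(matrix, clinical, labels, base_panel = character(0),
                              alpha = 0.05, min_freq = 0.3, reduce = FALSE,
                              cv_folds = 5, seed = 1, min_panel = 5,
                              tolerance = 0.002, min_cases = 10) {
  lab <- labels[labels$label %in% c("rapid", "stable"), ]
  strata_present <- sort(unique(lab$stratum))
  counts <- table(factor(lab$stratum, levels = 1:7), lab$label)
  eligible <- strata_present[counts[strata_present, "rapid"] >= 2 &
                               counts[strata_present, "stable"] >= 2]
  skipped <- setdiff(strata_present, eligible)
  for (s in skipped) {
    warning(sprintf("stratum %d skipped: missing or near-empty outcome class", s),
            call. = FALSE)
  }
  if (length(eligible) < 2) stopf("need at least 2 strata with both classes")

  models <- list()
  grid_rows <- list()
  for (s_tr in eligible) {
    disc <- discover_stratum(matrix, lab, s_tr, alpha = alpha,
                             min_freq = min_freq, seed = seed)
    panel <- build_candidate_panel(disc, base_panel)
    lab_tr <- lab[lab$stratum == s_tr, ]
    model <- if (reduce && nrow(panel) > min_panel) {
      take_one_out_reduce(matrix, lab_tr, panel, cv_folds = cv_folds,
                          seed = seed, min_panel = min_panel,
                          tolerance = tolerance, stratum = s_tr)
    } else {
      train_svm(matrix, lab_tr, panel, cv_folds = cv_folds, seed = seed,
                stratum = s_tr)
    }
    models[[as.character(s_tr)]] <- list(model = model, discovery = disc,
                                         panel = panel)
    for (s_va in eligible) {
      lab_va <- lab[lab$stratum == s_va, ]
      sc <- score(model, matrix, sample_ids = lab_va$patient_id)
      rr <- roc_auc(sc, lab_va$label)
      grid_rows[[length(grid_rows) + 1]] <- data.frame(
        train_stratum = s_tr, val_stratum = s_va,
        auc = rr$auc, ci_low = rr$ci_low, ci_high = rr$ci_high,
        n_cases = rr$n_cases, n_controls = rr$n_controls,
        panel_size = length(model$panel),
        is_training_set = s_tr == s_va,
        underpowered = rr$n_cases < min_cases
      )
    }
  }
  grid <- do.call(rbind, grid_rows)

  # best externally trained subclassifier per validation stratum
  best_rows <- lapply(eligible, function(s_va) {
    g <- grid[grid$val_stratum == s_va & grid$train_stratum != s_va, ]
    if (!nrow(g)) return(NULL)
    g$adjacency <- abs(g$train_stratum - s_va)
    g <- g[order(-g$auc, g$adjacency, g$train_stratum), ]
    out <- g[1, c("train_stratum", "val_stratum", "auc", "ci_low", "ci_high",
                  "n_cases", "n_controls", "underpowered")]
    names(out)[names(out) == "train_stratum"] <- "best_train_stratum"
    out
  })
  best <- do.call(rbind, best_rows)

  # comparators per validation stratum
  cl <- clinical[match(lab$patient_id, clinical$patient_id), ]
  kfre <- kfre_risk(age = cl$age, sex = cl$sex, egfr = cl$baseline_egfr,
                    acr = cl$acr)
  comp_rows <- lapply(eligible, function(s_va) {
    in_s <- lab$stratum == s_va
    l <- lab$label[in_s]
    base_model <- if (length(base_panel) >= 2) {
      train_svm(matrix, lab[lab$stratum != s_va, ], base_panel,
                cv_folds = cv_folds, seed = seed, stratum = NA)
    }
    data.frame(
      val_stratum = s_va,
      auc_albuminuria = roc_auc(cl$uae[in_s], l)$auc,
      auc_base_panel = if (!is.null(base_model)) {
        roc_auc(score(base_model, matrix, sample_ids = lab$patient_id[in_s]), l)$auc
      } else {
        NA_real_
      },
      auc_kfre_2yr = roc_auc(kfre$risk_2yr[in_s], l)$auc,
      auc_kfre_5yr = roc_auc(kfre$risk_5yr[in_s], l)$auc
    )
  })
  comparators <- do.call(rbind, comp_rows)

  structure(list(grid = grid, best = best, comparators = comparators,
                 models = models, skipped = skipped),
            class = "validation_grid")
}

#' @export
print.validation_grid <- function(x, ...) {
  cat(sprintf("validation_grid: %d train strata x %d validation strata\n",
              length(unique(x$grid$train_stratum)),
              length(unique(x$grid$val_stratum))))
  print(x$best, row.names = FALSE)
  invisible(x)
}
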