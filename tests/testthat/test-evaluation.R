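test_that("AUC equals pairwise concordance, including tied scores", {
  set.seed(13)
  for (i in 1:20) {
    n <- sample(20:60, 1)
    is_case <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.4, 0.6))
    if (!any(is_case) || all(is_case)) next
    scores <- round(rnorm(n, mean = is_case), sample(c(0, 1, 3), 1))
    rr <- roc_auc(scores, is_case)
    expect_equal(rr$auc, pairwise_auc_oracle(scores, is_case),
                 tolerance = 1e-12)
    expect_lte(rr$ci_low, rr$auc)
    expect_gte(rr$ci_high, rr$auc)
    expect_gte(rr$ci_low, 0)
    expect_lte(rr$ci_high, 1)
  }
})

test_that("perfectly separated scores give AUC 1 and a perfect operating point", {
  scores <- c(5, 6, 7, 1, 2, 3)
  labels <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  expect_equal(roc_auc(scores, labels)$auc, 1.0)
  op <- operating_point(scores, labels)
  expect_equal(op$sensitivity, 1)
  expect_equal(op$specificity, 1)
  expect_false(op$degenerate)
  expect_error(roc_auc(scores, rep(TRUE, 6)), "both classes")
})

test_that("the Youden operating point matches the hand-enumerated threshold search", {
  scores <- c(0.9, 0.8, 0.2, 0.1)
  labels <- c(TRUE, TRUE, FALSE, FALSE)
  op <- operating_point(scores, labels)
  expect_gt(op$threshold, 0.2)
  expect_lte(op$threshold, 0.8)
  expect_equal(op$ppv, 1)
  expect_equal(op$npv, 1)
  # constant scores carry no information and are flagged
  op0 <- operating_point(rep(1, 6), c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_true(op0$degenerate)
  expect_equal(op0$youden, 0, tolerance = 1e-12)
})

test_that("identical or monotone-transformed scores compare as equal AUCs", {
  set.seed(14)
  scores <- rnorm(80)
  labels <- runif(80) < plogis(scores)
  if (!any(labels) || all(labels)) labels[1:2] <- c(TRUE, FALSE)
  cmp_same <- compare_auc(scores, scores, labels, paired = TRUE)
  expect_equal(cmp_same$auc_difference, 0)
  expect_equal(cmp_same$p_value, 1)
  cmp_mono <- compare_auc(scores, exp(scores) + 5, labels, paired = TRUE)
  expect_equal(cmp_mono$auc_difference, 0)
  expect_error(compare_auc(scores, scores[-1], labels, paired = TRUE),
               "equal-length")
})

test_that("the cross-stratum grid covers every train/validation pair correctly", {
  cfg <- tiny_config(
    n_patients = 360, n_peptides = 90, n_housekeeping = 10,
    n_planted_per_stratum = 8, planted_log2_effect = 1.2,
    stratum_weights = c(1, 1, 1, 0, 0, 0, 0) / 3,
    rapid_fraction_per_stratum = rep(0.35, 7),
    visit_noise_sd = 0, seed = 55
  )
  coh <- generate_cohort(cfg)
  norm <- normalize_matrix(coh$matrix)
  labels <- label_cohort(coh$clinical, coh$trajectories)
  vg <- cross_stratum_run(norm, coh$clinical, labels,
                          base_panel = c("pep_0060", "pep_0061", "pep_0062"),
                          cv_folds = 3, seed = 9)
  k <- length(unique(vg$grid$train_stratum))
  expect_equal(nrow(vg$grid), k * k)
  expect_equal(sum(vg$grid$is_training_set), k)
  expect_equal(sum(!vg$grid$is_training_set), k * (k - 1))

  # validation samples are never the training samples (strata partition)
  lab_cc <- labels[labels$label %in% c("rapid", "stable"), ]
  ids_by_stratum <- split(lab_cc$patient_id, lab_cc$stratum)
  off <- vg$grid[!vg$grid$is_training_set, ]
  for (r in seq_len(nrow(off))) {
    expect_length(intersect(ids_by_stratum[[as.character(off$train_stratum[r])]],
                            ids_by_stratum[[as.character(off$val_stratum[r])]]), 0)
  }

  # each validation stratum gets a best external model and comparator AUCs
  expect_setequal(vg$best$val_stratum, unique(vg$grid$val_stratum))
  expect_true(all(vg$best$best_train_stratum != vg$best$val_stratum))
  expect_true(all(is.finite(vg$comparators$auc_albuminuria)))
  expect_true(all(is.finite(vg$comparators$auc_kfre_2yr)))
})
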