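# Small separable fixture: cases uniformly higher on both panel peptides.
separable_fixture <- function(n = 40, seed = 5) {
  set.seed(seed)
  n_case <- n / 2
  amp <- cbind(
    pA = c(exp(rnorm(n_case, 6, 0.3)), exp(rnorm(n - n_case, 3, 0.3))),
    pB = c(exp(rnorm(n_case, 5.5, 0.3)), exp(rnorm(n - n_case, 2.5, 0.3))),
    pC = exp(rnorm(n, 4, 1))  # uninformative
  )
  rownames(amp) <- sprintf("s%02d", 1:n)
  labels <- data.frame(
    patient_id = rownames(amp),
    label = rep(c("rapid", "stable"), each = n_case),
    stratum = 1L, stringsAsFactors = FALSE
  )
  list(matrix = make_matrix(amp), labels = labels,
       is_case = rep(c(TRUE, FALSE), each = n_case))
}

test_that("a separable toy problem is fit perfectly and scores order correctly", {
  fx <- separable_fixture()
  m <- train_svm(fx$matrix, fx$labels, c("pA", "pB"), seed = 2)
  sc <- score(m, fx$matrix)
  expect_equal(auc <- roc_auc(sc, fx$labels$label)$auc, 1.0)
  expect_gt(min(sc[fx$is_case]), max(sc[!fx$is_case]))
})

test_that("scores are invariant to peptide order and impute missing peptides as undetected", {
  fx <- separable_fixture()
  m <- train_svm(fx$matrix, fx$labels, c("pA", "pB"), seed = 2)
  sc <- score(m, fx$matrix)
  shuffled <- fx$matrix$amplitudes[, c("pC", "pB", "pA")]
  expect_equal(score(m, shuffled), sc, ignore_attr = TRUE, tolerance = 1e-12)
  # single profile, names in arbitrary order
  prof <- c(pB = 100, pA = 400)
  expect_equal(score(m, prof), score(m, c(pA = 400, pB = 100)),
               tolerance = 1e-12, ignore_attr = TRUE)
  # a missing panel peptide is scored as non-detected and counted
  dropped <- score(m, fx$matrix$amplitudes[, "pA", drop = FALSE])
  expect_equal(attr(dropped, "n_missing_peptides"), 1)
  expect_true(all(is.finite(dropped)))
})

test_that("training is deterministic and invariant to sample order", {
  fx <- two_group_matrix(n_case = 25, n_control = 35, n_peptides = 20,
                         planted = 1:4, log2_effect = 1.2, seed = 21)
  panel <- sprintf("p%03d", 1:8)
  m1 <- train_svm(fx$matrix, fx$labels, panel, seed = 4)
  m2 <- train_svm(fx$matrix, fx$labels, panel, seed = 4)
  sc1 <- score(m1, fx$matrix)
  expect_equal(score(m2, fx$matrix), sc1, tolerance = 1e-12)

  perm <- sample(nrow(fx$matrix$amplitudes))
  pm_perm <- make_matrix(fx$matrix$amplitudes[perm, ])
  m3 <- train_svm(pm_perm, fx$labels[perm, ], panel, seed = 4)
  expect_equal(score(m3, fx$matrix)[names(sc1)], sc1, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("cross-validated AUC is near chance when labels are permuted", {
  fx <- two_group_matrix(n_case = 60, n_control = 60, n_peptides = 15,
                         planted = 1:5, log2_effect = 1.5, seed = 31)
  set.seed(99)
  shuffled <- fx$labels
  shuffled$label <- sample(shuffled$label)
  m <- train_svm(fx$matrix, shuffled, sprintf("p%03d", 1:15), seed = 6)
  expect_gt(m$metadata$cv_auc, 0.35)
  expect_lt(m$metadata$cv_auc, 0.68)
})

test_that("models survive a JSON round-trip with identical scores", {
  fx <- separable_fixture()
  m <- train_svm(fx$matrix, fx$labels, c("pA", "pB", "pC"), seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  set.seed(12)
  profiles <- matrix(exp(rnorm(300, 4, 2)), 100, 3,
                     dimnames = list(NULL, c("pA", "pB", "pC")))
  expect_lt(max(abs(score(m2, profiles) - score(m, profiles))), 1e-12)

  # unknown schema versions are refused outright
  bad <- jsonlite::read_json(path)
  bad$schema_version <- 99
  path2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(bad, path2, auto_unbox = TRUE, digits = NA)
  expect_error(load_model(path2), "schema")
})

test_that("take-one-out never grows the panel and honours the floor", {
  fx <- two_group_matrix(n_case = 30, n_control = 40, n_peptides = 12,
                         planted = 1:3, log2_effect = 1.5, seed = 41)
  panel <- sprintf("p%03d", 1:6)
  # panel already at min_panel: returned unchanged
  m_floor <- take_one_out_reduce(fx$matrix, fx$labels, panel,
                                 cv_folds = 3, min_panel = 6, seed = 2)
  expect_setequal(m_floor$panel, panel)

  m <- take_one_out_reduce(fx$matrix, fx$labels, panel,
                           cv_folds = 3, min_panel = 2, seed = 2)
  expect_lte(length(m$panel), length(panel))
  # the incumbent-best objective trace is non-decreasing
  expect_true(all(diff(m$trace$best_objective) >= -1e-12))
  expect_error(
    take_one_out_reduce(fx$matrix, fx$labels, panel, min_panel = 10),
    "min_panel"
  )
})
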