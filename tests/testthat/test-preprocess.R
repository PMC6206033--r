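test_that("normalization reproduces the hand-computed toy factors", {
  # 3 samples whose detected housekeeping means are 2, 4, 6; grand mean 4.
  # With the grand-mean reference, sample factors are 0.5, 1, 1.5 and each
  # amplitude is divided by its sample's factor.
  amp <- rbind(
    s1 = c(hk1 = 1, hk2 = 3, p1 = 10, p2 = 0),
    s2 = c(hk1 = 3, hk2 = 5, p1 = 8, p2 = 2),
    s3 = c(hk1 = 5, hk2 = 7, p1 = 0, p2 = 6)
  )
  pm <- peptide_matrix(amp, housekeeping_ids = c("hk1", "hk2"))
  out <- normalize_matrix(pm, reference = "grand_mean")
  expected <- amp * (4 / c(2, 4, 6))
  expect_equal(out$amplitudes, expected, tolerance = 1e-12)
  expect_equal(attr(out, "normalization")$reference_value, 4)
})

test_that("a matrix with equal housekeeping means is unchanged under the grand-mean reference", {
  amp <- rbind(
    s1 = c(hk1 = 2, hk2 = 4, p1 = 7),
    s2 = c(hk1 = 4, hk2 = 2, p1 = 1),
    s3 = c(hk1 = 3, hk2 = 3, p1 = 9)
  )
  pm <- peptide_matrix(amp, housekeeping_ids = c("hk1", "hk2"))
  out <- normalize_matrix(pm, reference = "grand_mean")
  expect_equal(out$amplitudes, amp, tolerance = 1e-12)
})

test_that("normalization is invariant to per-sample rescaling and idempotent", {
  coh <- generate_cohort(tiny_config(n_patients = 40))
  pm <- coh$matrix
  scaled <- pm$amplitudes
  scaled["pt_00003", ] <- scaled["pt_00003", ] * 10
  scaled["pt_00011", ] <- scaled["pt_00011", ] * 0.04
  pm_scaled <- peptide_matrix(scaled, pm$housekeeping_ids)

  n1 <- normalize_matrix(pm)
  n2 <- normalize_matrix(pm_scaled)
  expect_equal(n1$amplitudes, n2$amplitudes, tolerance = 1e-10)

  twice <- normalize_matrix(n1)
  expect_equal(twice$amplitudes, n1$amplitudes, tolerance = 1e-10)
})

test_that("normalization keeps zeros at zero and preserves within-sample ratios", {
  coh <- generate_cohort(tiny_config(n_patients = 30))
  out <- normalize_matrix(coh$matrix)
  amp <- coh$matrix$amplitudes
  expect_identical(out$amplitudes == 0, amp == 0)
  s <- amp["pt_00007", ]
  o <- out$amplitudes["pt_00007", ]
  nz <- s > 0
  ratios_in <- s[nz] / s[nz][1]
  ratios_out <- o[nz] / o[nz][1]
  expect_equal(ratios_out, ratios_in, tolerance = 1e-12)
})

test_that("a sample with no detected housekeeping peptide is reported by id", {
  amp <- rbind(s1 = c(hk1 = 2, p1 = 5), s2 = c(hk1 = 0, p1 = 3))
  pm <- peptide_matrix(amp, housekeeping_ids = "hk1")
  expect_error(normalize_matrix(pm), "s2")
  pm_nohk <- peptide_matrix(amp)
  expect_error(normalize_matrix(pm_nohk), "housekeeping")
})

test_that("peptide summaries apply the amplitude-times-frequency rule", {
  amp <- rbind(
    c1 = c(p = 2), c2 = c(p = 4), c3 = c(p = 0), c4 = c(p = 0),
    k1 = c(p = 3), k2 = c(p = 3), k3 = c(p = 0), k4 = c(p = 3)
  )
  pm <- make_matrix(amp)
  s <- peptide_summary(pm, paste0("c", 1:4), paste0("k", 1:4), "p")
  expect_equal(s$mean_amplitude_cases, 3)
  expect_equal(s$frequency_cases, 0.5)
  expect_equal(s$mean_relative_abundance_cases, 1.5)
  expect_equal(s$frequency_controls, 0.75)
  expect_equal(s$fold_change, 1)  # identical detected means
  expect_true(s$fold_change_defined)
})

test_that("peptide summaries flag undefined fold changes and reject bad input", {
  amp <- rbind(
    c1 = c(p = 2, q = 1), c2 = c(p = 4, q = 1),
    k1 = c(p = 0, q = 1), k2 = c(p = 0, q = 1)
  )
  pm <- make_matrix(amp)
  s <- peptide_summary(pm, c("c1", "c2"), c("k1", "k2"), "p")
  expect_true(is.na(s$fold_change))
  expect_false(s$fold_change_defined)
  expect_error(peptide_summary(pm, c("c1", "c2"), c("k1", "k2"), "zz"), "absent")
  expect_error(peptide_summary(pm, c("c1", "k1"), c("k1", "k2"), "p"), "overlap")
})

test_that("peptide summaries are invariant to sample order", {
  coh <- generate_cohort(tiny_config(n_patients = 30))
  ids <- rownames(coh$matrix$amplitudes)
  cases <- ids[1:10]
  controls <- ids[11:30]
  pep <- "pep_0005"
  a <- peptide_summary(coh$matrix, cases, controls, pep)
  b <- peptide_summary(coh$matrix, rev(cases), sample(controls), pep)
  expect_equal(a, b)
})
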