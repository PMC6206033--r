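test_that("noiseless trajectories are exact lines and round-trip the slope", {
  tr <- generate_trajectory(90, -5, n_visits = 3, visit_noise_sd = 0,
                            followup_years = 2)
  expect_equal(tr$time, c(0, 1, 2))
  expect_equal(tr$egfr, c(90, 85, 80))
  expect_equal(estimate_slope(tr), -5)

  tr2 <- generate_trajectory(70, 2.5, n_visits = 6, visit_noise_sd = 0,
                             followup_years = 4)
  expect_equal(estimate_slope(tr2), 2.5, tolerance = 1e-12)
  expect_equal(tr2$time[1], 0)
  expect_true(all(diff(tr2$time) > 0))

  expect_error(generate_trajectory(90, -5, n_visits = 1, visit_noise_sd = 0),
               "n_visits")
  expect_error(generate_trajectory(-1, -5, n_visits = 3, visit_noise_sd = 0),
               "baseline")
})

test_that("the least-squares slope of noisy trajectories is unbiased", {
  true_slope <- -4
  slopes <- vapply(1:400, function(i) {
    tr <- generate_trajectory(80, true_slope, n_visits = 5,
                              visit_noise_sd = 3, followup_years = 3,
                              seed = 5000 + i)
    estimate_slope(tr)
  }, numeric(1))
  mc_se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - true_slope), 4 * mc_se + 0.05)
})

test_that("cohort generation is bit-reproducible under a fixed seed", {
  cfg <- tiny_config(n_patients = 60)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$matrix$amplitudes, b$matrix$amplitudes)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$trajectories, b$trajectories)
  expect_identical(a$truth, b$truth)
})

test_that("stratum and outcome proportions converge to the configured fractions", {
  cfg <- cohort_config(
    n_patients = 5000, n_peptides = 30, n_housekeeping = 6,
    n_planted_per_stratum = 2, seed = 77
  )
  coh <- generate_cohort(cfg)
  cl <- coh$clinical
  # stratum weights within 3 binomial SE
  for (s in 1:7) {
    w <- cfg$stratum_weights[s]
    se <- sqrt(w * (1 - w) / nrow(cl))
    expect_lt(abs(mean(cl$true_stratum == s) - w), 3 * se + 1e-9,
              label = sprintf("stratum %d weight", s))
  }
  # rapid fraction within the large strata (incl. the 129/479 reference)
  for (s in 1:3) {
    in_s <- cl$true_stratum == s
    rf <- cfg$rapid_fraction_per_stratum[s]
    se <- sqrt(rf * (1 - rf) / sum(in_s))
    expect_lt(abs(mean(cl$true_group[in_s] == "rapid") - rf), 3 * se,
              label = sprintf("stratum %d rapid fraction", s))
  }
})

test_that("generated cohorts respect the structural invariants", {
  coh <- generate_cohort(tiny_config(n_patients = 80))
  amp <- coh$matrix$amplitudes
  expect_true(all(amp >= 0))
  hk <- coh$matrix$housekeeping_ids
  expect_true(all(amp[, hk] > 0))  # housekeeping always detected
  expect_length(intersect(unlist(coh$truth$planted_ids), hk), 0)
  # baseline eGFR equals the trajectory value at time 0
  t0 <- coh$trajectories[coh$trajectories$time == 0, ]
  m <- match(coh$clinical$patient_id, t0$patient_id)
  expect_equal(coh$clinical$baseline_egfr, t0$egfr[m], tolerance = 1e-12)
  # trajectories: >= 2 visits, strictly increasing times starting at 0
  by_pt <- split(coh$trajectories$time, coh$trajectories$patient_id)
  expect_true(all(vapply(by_pt, length, integer(1)) >= 2))
  expect_true(all(vapply(by_pt, function(t) t[1] == 0 && all(diff(t) > 0),
                         logical(1))))
})

test_that("invalid configurations are rejected", {
  expect_error(tiny_config(stratum_weights = rep(0.2, 7)), "summing to 1")
  expect_error(tiny_config(slope_rapid_range = c(-12, -4)), "below -5")
  expect_error(tiny_config(slope_stable_range = c(-3, 5)), "within")
  expect_error(tiny_config(n_housekeeping = 80), "smaller")
  expect_error(tiny_config(n_planted_per_stratum = 40, planted_overlap = 0),
               "exceed")
  expect_error(tiny_config(detect_prob_background = 0), "detect_prob")
  expect_error(tiny_config(n_visits_range = c(1, 5)), "n_visits_range")
})

test_that("a larger planted effect never decreases the Bayes-optimal AUC", {
  aucs <- vapply(c(0, 0.5, 1, 2), function(eff) {
    coh <- generate_cohort(tiny_config(n_patients = 10,
                                       planted_log2_effect = eff))
    bayes_auc_oracle(coh$truth, 1, n = 2e4, seed = 11)
  }, numeric(1))
  expect_equal(aucs[1], 0.5, tolerance = 0.02)  # null generator
  expect_true(all(diff(aucs) > -0.01))
  expect_gt(aucs[4], aucs[2])
})

test_that("cohorts round-trip through the plain-text formats", {
  coh <- generate_cohort(tiny_config(n_patients = 25))
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_equal(back$matrix$amplitudes, coh$matrix$amplitudes, tolerance = 1e-12)
  expect_identical(back$matrix$housekeeping_ids, coh$matrix$housekeeping_ids)
  expect_equal(back$clinical$uae, coh$clinical$uae, tolerance = 1e-12)
  expect_identical(back$truth$planted_ids$stratum_1,
                   coh$truth$planted_ids$stratum_1)
})

test_that("configs load from YAML and JSON with defaults preserved", {
  dir <- withr::local_tempdir()
  yml <- file.path(dir, "cfg.yaml")
  writeLines(c("n_patients: 50", "n_peptides: 200", "seed: 9"), yml)
  cfg <- read_cohort_config(yml)
  expect_equal(cfg$n_patients, 50L)
  expect_equal(cfg$n_housekeeping, 29L)  # default untouched
  js <- file.path(dir, "cfg.json")
  jsonlite::write_json(list(n_patients = 50, n_peptides = 200, seed = 9), js,
                       auto_unbox = TRUE)
  cfg2 <- read_cohort_config(js)
  expect_equal(cfg2$n_patients, cfg$n_patients)
  writeLines(c("bogus_field: 1"), yml)
  expect_error(read_cohort_config(yml), "unknown config fields")
})
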