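test_that("rank-sum p-values match the exact enumeration on canonical cases", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6)), 0.1, tolerance = 1e-12)
  # symmetry of the two-sided test
  expect_equal(wilcoxon_rank_sum(c(4, 5, 6), c(1, 2, 3)),
               wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6)), tolerance = 1e-12)
  # identical multisets: maximal p
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")
})

test_that("rank-sum p-values equal the brute-force permutation oracle (tie-free)", {
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(2:6, 1)
    m <- sample(2:6, 1)
    x <- rnorm(n)
    y <- rnorm(m, mean = runif(1, -1, 1))
    expect_equal(wilcoxon_rank_sum(x, y), enumerate_wilcoxon_p(x, y),
                 tolerance = 1e-12,
                 label = sprintf("n=%d m=%d rep=%d", n, m, rep))
  }
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(7)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), bh_stepup_oracle(p), tolerance = 1e-12)
  }
})

test_that("BH is permutation-equivariant and monotone in each p-value", {
  set.seed(8)
  p <- runif(20)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  perm <- sample(20)
  expect_equal(bh_adjust(p[perm]), q[perm], tolerance = 1e-12)
  # raising one p never lowers any q
  for (i in c(1, 7, 20)) {
    p2 <- p
    p2[i] <- min(1, p[i] + 0.2)
    expect_true(all(bh_adjust(p2) >= q - 1e-12))
  }
})

test_that("stratum discovery selects planted peptides and respects the frequency filter", {
  fx <- two_group_matrix(n_case = 60, n_control = 90, n_peptides = 40,
                         planted = 1:5, log2_effect = 2, seed = 3)
  d <- discover_stratum(fx$matrix, fx$labels, 1)
  tab <- d$table
  expect_true(all(tab$q_value >= tab$p_value))
  # q monotone in p rank
  o <- order(tab$p_value)
  expect_true(all(diff(tab$q_value[o]) >= -1e-12))
  planted_ids <- sprintf("p%03d", 1:5)
  expect_gte(sum(tab$selected[tab$peptide_id %in% planted_ids]), 4)
  # rarely detected peptides can never pass the frequency filter
  amp <- fx$matrix$amplitudes
  amp[, "p040"] <- 0
  idx <- c(1:5, 61:66)  # ~8% of cases, ~7% of controls
  amp[idx, "p040"] <- exp(rnorm(length(idx), 8, 0.1) +
                            3 * (idx <= 60))
  d2 <- discover_stratum(make_matrix(amp), fx$labels, 1, min_freq = 0.3)
  expect_false(d2$table$selected[d2$table$peptide_id == "p040"])
  expect_error(discover_stratum(fx$matrix, fx$labels, 5), "lacks cases")
})

test_that("consistent-regulation filtering only keeps direction-stable peptides", {
  fx <- two_group_matrix(n_case = 50, n_control = 80, n_peptides = 30,
                         planted = 1:4, log2_effect = 2.2, seed = 9)
  d <- discover_stratum(fx$matrix, fx$labels, 1,
                        require_consistent_regulation = TRUE, cv_folds = 3)
  sel <- d$table$peptide_id[d$table$selected]
  expect_gte(length(intersect(sel, sprintf("p%03d", 1:4))), 3)
})

test_that("candidate panels are the provenance-tagged union of base and discoveries", {
  fx <- two_group_matrix(n_case = 50, n_control = 80, n_peptides = 30,
                         planted = 1:4, log2_effect = 1.5, seed = 10)
  d <- discover_stratum(fx$matrix, fx$labels, 1)
  sel <- d$table$peptide_id[d$table$selected]
  base <- c("p020", "p021", sel[1])

  panel <- build_candidate_panel(d, base)
  expect_identical(panel$peptide_id[1:3], base)  # base panel first
  expect_false(anyDuplicated(panel$peptide_id) > 0)
  expect_equal(nrow(panel), length(union(base, sel)))
  expect_identical(panel$provenance[panel$peptide_id == sel[1]],
                   "base_panel+stratum_discovery")
  # discoveries ordered by ascending q
  disc_part <- panel$peptide_id[panel$provenance == "stratum_discovery"]
  qs <- d$table$q_value[match(disc_part, d$table$peptide_id)]
  expect_true(all(diff(qs) >= -1e-12))

  # empty discovery: panel equals the base panel
  null_d <- d
  null_d$table$selected <- FALSE
  p0 <- build_candidate_panel(null_d, base)
  expect_identical(p0$peptide_id, base)
  expect_identical(build_candidate_panel(NULL, base)$peptide_id, base)
})

test_that("top_differential ranks by q, |log2 FC|, then id, deterministically", {
  fx <- two_group_matrix(n_case = 40, n_control = 60, n_peptides = 20,
                         planted = 1:3, log2_effect = 1.5, seed = 11)
  d <- discover_stratum(fx$matrix, fx$labels, 1)
  top_all <- top_differential(d, k = 100)
  expect_equal(nrow(top_all), 20)  # k beyond the peptide count returns all
  top3 <- top_differential(d, k = 3)
  expect_identical(top3$peptide_id, top_all$peptide_id[1:3])

  # forced ties break lexicographically and reproducibly
  d2 <- d
  d2$table$q_value[] <- 0.5
  d2$table$fold_change[] <- 2
  t1 <- top_differential(d2, k = 5)
  t2 <- top_differential(d2, k = 5)
  expect_identical(t1$peptide_id, sort(d2$table$peptide_id)[1:5])
  expect_identical(t1, t2)
})
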