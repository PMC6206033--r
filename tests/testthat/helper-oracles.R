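# Independent brute-force oracles used to check the package's statistics.
# These are written directly from the defining formulas and share no code
# with the implementation paths they verify.

# Exact two-sided Wilcoxon rank-sum p-value by full enumeration of all
# C(n+m, n) group assignments of the pooled values.
enumerate_wilcoxon_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2  # Mann-Whitney U of x
  idx <- utils::combn(length(pooled), n)
  w_all <- apply(idx, 2, function(ix) sum(r[ix]) - n * (n + 1) / 2)
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Monte-Carlo permutation two-sided p-value for the rank-sum statistic.
# Also returns the estimated probability mass of the lattice atom at the
# observed statistic: a continuity-corrected normal approximation can
# differ from the discrete permutation p by up to one atom, so comparisons
# should allow for it in addition to the Monte-Carlo standard error.
mc_permutation_p <- function(x, y, B = 4000) {
  pooled <- c(x, y)
  n <- length(x)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n)])
  mu <- n * (length(pooled) + 1) / 2
  dev_obs <- abs(w_obs - mu)
  dev <- replicate(B, abs(sum(r[sample(length(pooled), n)]) - mu))
  list(p = mean(dev >= dev_obs - 1e-9),
       atom = mean(abs(dev - dev_obs) < 1))
}

# Benjamini-Hochberg step-up adjustment written from the definition:
# q_(i) = min_{j >= i} m p_(j) / j, capped at 1, in input order.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# AUC as the mean over all case-control pairs of 1 / 0.5 / 0 concordance.
pairwise_auc_oracle <- function(scores, is_case) {
  sc <- scores[is_case]
  sn <- scores[!is_case]
  total <- 0
  for (a in sc) {
    total <- total + sum(a > sn) + 0.5 * sum(a == sn)
  }
  total / (length(sc) * length(sn))
}

# Independently coded published 4-variable kidney-failure risk equation.
kfre_oracle <- function(age, male, egfr, acr, horizon, north_american) {
  xb <- -0.2201 * (age / 10 - 7.036) +
    0.2467 * (ifelse(male, 1, 0) - 0.5642) -
    0.5567 * (egfr / 5 - 7.222) +
    0.4510 * (log(max(acr, 1)) - 5.137)
  base <- if (north_american) {
    if (horizon == 2) 0.9832 else 0.9365
  } else {
    if (horizon == 2) 0.9878 else 0.9570
  }
  1 - base^exp(xb)
}

# Independently coded 2009 creatinine eGFR equation (non-Black form).
ckd_epi_oracle <- function(scr, age, female) {
  k <- if (female) 0.7 else 0.9
  a <- if (female) -0.329 else -0.411
  val <- 141 * min(scr / k, 1)^a * max(scr / k, 1)^(-1.209) * 0.993^age
  if (female) val <- val * 1.018
  val
}

# Closed-form OLS slope from the normal equations (independent arithmetic).
ols_slope_oracle <- function(t, y) {
  n <- length(t)
  (n * sum(t * y) - sum(t) * sum(y)) / (n * sum(t^2) - sum(t)^2)
}
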