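# Ground-truth oracles for the synthetic generator. These score patients
# with the true likelihood ratio of the generative model, giving the
# Bayes-optimal classifier that any trained model is benchmarked against.

#' True log-likelihood-ratio score under the generative model
#'
#' For the planted peptides of one stratum, computes log LR(case vs
#' control) of a profile under the generator's zero-inflated log-normal
#' model: a non-detection contributes log((1-p1)/(1-p0)); a detected
#' amplitude contributes log(p1/p0) plus the log-normal density ratio at
#' the shifted vs baseline log-mean. Non-planted peptides are identically
#' distributed in both groups and contribute nothing.
#'
#' @param amp numeric matrix (samples x peptides) of raw amplitudes,
#'   colnames covering the stratum's planted peptide ids
#' @param truth ground truth from [generate_cohort()]
#' @param stratum stratum id 1..7
#' @return numeric vector of log-likelihood ratios, one per row
#' @export
likelihood_ratio_score <- function(amp, truth, stratum) {
  ids <- truth$planted_ids[[paste0("stratum_", stratum)]]
  if (!length(ids)) return(numeric(nrow(amp)))
  eff <- truth$planted_effect_per_stratum[stratum] *
    truth$planted_sign[ids]
  delta <- eff * log(2)
  p0 <- rep(truth$detect_prob_background, length(ids))
  p1 <- if (isTRUE(truth$effect_on_detection)) {
    plogis(qlogis(p0) + truth$detection_effect_scale * eff)
  } else {
    p0
  }
  mu <- truth$peptide_mu[ids]
  sdl <- truth$amplitude_log_sd
  x <- amp[, ids, drop = FALSE]
  llr <- numeric(nrow(amp))
  for (j in seq_along(ids)) {
    v <- x[, j]
    det <- v > 0
    contrib <- numeric(length(v))
    contrib[!det] <- log(1 - p1[j]) - log(1 - p0[j])
    if (any(det)) {
      lv <- log(v[det])
      contrib[det] <- log(p1[j]) - log(p0[j]) +
        dnorm(lv, mu[j] + delta[j], sdl, log = TRUE) -
        dnorm(lv, mu[j], sdl, log = TRUE)
    }
    llr <- llr + contrib
  }
  unname(llr)
}

# Sample n profiles of the stratum's planted peptides for one outcome group
# directly from the generative model (only planted columns matter for the
# likelihood ratio).
sample_planted_profiles <- function(truth, stratum, n, rapid) {
  ids <- truth$planted_ids[[paste0("stratum_", stratum)]]
  eff <- truth$planted_effect_per_stratum[stratum] * truth$planted_sign[ids]
  delta <- if (rapid) eff * log(2) else numeric(length(ids))
  p0 <- rep(truth$detect_prob_background, length(ids))
  p_det <- if (rapid && isTRUE(truth$effect_on_detection)) {
    plogis(qlogis(p0) + truth$detection_effect_scale * eff)
  } else {
    p0
  }
  mu <- truth$peptide_mu[ids]
  out <- matrix(0, n, length(ids), dimnames = list(NULL, ids))
  for (j in seq_along(ids)) {
    det <- runif(n) < p_det[j]
    out[det, j] <- rlnorm(sum(det), mu[j] + delta[j], truth$amplitude_log_sd)
  }
  out
}

#' Bayes-optimal AUC of the generator for one stratum
#'
#' Brute-force oracle: draws `n` fresh case and `n` fresh control profiles
#' of the stratum's planted peptides straight from the generative model,
#' scores both with the true likelihood ratio, and returns the rank-sum
#' AUC. By the Neyman-Pearson lemma no classifier can exceed this AUC on
#' data from the same generator (up to Monte-Carlo error).
#'
#' @param truth ground truth from [generate_cohort()]
#' @param stratum stratum id 1..7
#' @param n samples per group (default 1e5)
#' @param seed RNG seed for the fresh draw
#' @return the Monte-Carlo Bayes-optimal AUC
#' @export
bayes_auc_oracle <- function(truth, stratum, n = 1e5, seed = 1) {
  with_seed(seed, {
    cases <- sample_planted_profiles(truth, stratum, n, rapid = TRUE)
    controls <- sample_planted_profiles(truth, stratum, n, rapid = FALSE)
  })
  s_case <- likelihood_ratio_score(cases, truth, stratum)
  s_ctrl <- likelihood_ratio_score(controls, truth, stratum)
  auc_rank(c(s_case, s_ctrl), c(rep(TRUE, n), rep(FALSE, n)))
}
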