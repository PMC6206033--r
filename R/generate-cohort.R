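#' Simulate a longitudinal eGFR trajectory
#'
#' eGFR at visit time t is `baseline_egfr + true_slope * t` plus independent
#' Gaussian visit noise, floored at 1 ml/min/1.73 m^2. Visits are uniformly
#' spaced over the follow-up window, with the first visit at time 0, so the
#' baseline eGFR equals the (noise-free) trajectory value at time 0.
#'
#' @param baseline_egfr baseline eGFR (> 0), ml/min/1.73 m^2
#' @param true_slope eGFR change per year
#' @param n_visits number of visits (>= 2)
#' @param visit_noise_sd sd of per-visit measurement noise
#' @param followup_years time of the last visit (default 3 years)
#' @param seed optional seed; if NULL, draws from the current RNG stream
#' @return data.frame with columns `time` (years, strictly increasing,
#'   starting at 0) and `egfr`
#' @export
#' @examples
#' generate_trajectory(90, -5, n_visits = 3, visit_noise_sd = 0,
#'                     followup_years = 2)
generate_trajectory <- function(baseline_egfr, true_slope, n_visits,
                                visit_noise_sd, followup_years = 3,
                                seed = NULL) {
  if (!is_count(n_visits) || n_visits < 2) stopf("n_visits must be >= 2")
  if (baseline_egfr <= 0) stopf("baseline_egfr must be positive")
  if (followup_years <= 0) stopf("followup_years must be positive")
  draw <- function() {
    times <- seq(0, followup_years, length.out = n_visits)
    noise <- if (visit_noise_sd > 0) rnorm(n_visits, 0, visit_noise_sd) else rep(0, n_visits)
    noise[1] <- 0  # the time-0 visit defines the baseline eGFR exactly
    egfr <- pmax(baseline_egfr + true_slope * times + noise, 1)
    data.frame(time = times, egfr = egfr)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Generate a synthetic peptidomics cohort
#'
#' Draws a cohort with the joint structure the downstream analysis assumes:
#' each patient receives a baseline-eGFR stratum, a rapid/stable outcome
#' group, a true eGFR slope and noisy longitudinal trajectory, shifted
#' clinical covariates, and a zero-inflated log-normal peptide profile in
#' which the peptides planted for the patient's stratum are shifted
#' (amplitude and, optionally, detection probability) when the patient is a
#' rapid progressor. Housekeeping peptides are always detected and drawn
#' from the same low-variance distribution for every patient.
#'
#' All randomness derives from `config$seed` through named per-patient
#' substreams, so the output is reproducible bit-for-bit and independent of
#' execution order.
#'
#' @param config a [cohort_config()]
#' @return list with elements
#'   \describe{
#'     \item{matrix}{a `peptide_matrix`: amplitude matrix (samples x
#'       peptides, 0 = not detected) plus housekeeping ids}
#'     \item{clinical}{data.frame of per-patient covariates, baseline eGFR,
#'       follow-up, ground-truth group and stratum}
#'     \item{trajectories}{long data.frame (patient_id, time, egfr)}
#'     \item{truth}{generator ground truth: planted peptide ids per stratum,
#'       per-peptide effect signs and distribution parameters}
#'   }
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  cfg <- config
  nh <- cfg$n_housekeeping
  np <- cfg$n_peptides
  n_reg <- np - nh

  hk_ids <- sprintf("hk_%03d", seq_len(nh))
  reg_ids <- sprintf("pep_%04d", seq_len(n_reg))
  peptide_ids <- c(hk_ids, reg_ids)

  # peptide-level parameters from their own substream
  pep <- with_seed(substream_seed(cfg$seed, "peptides"), {
    list(
      mu = c(
        rnorm(nh, cfg$amplitude_log_mean, cfg$peptide_mean_sd / 2),
        rnorm(n_reg, cfg$amplitude_log_mean, cfg$peptide_mean_sd)
      ),
      sign = sample(c(-1, 1), n_reg, replace = TRUE)
    )
  })

  layout <- planted_layout(cfg)
  planted_ids <- lapply(layout, function(ix) reg_ids[ix])
  names(planted_ids) <- paste0("stratum_", 1:7)

  strata <- reference_strata()

  n <- cfg$n_patients
  amp <- matrix(0, nrow = n, ncol = np,
                dimnames = list(sprintf("pt_%05d", seq_len(n)), peptide_ids))
  clinical <- vector("list", n)
  traj <- vector("list", n)

  cs <- lapply(cfg$covariate_shift, function(v) rep_len(as.numeric(v), 7))

  for (i in seq_len(n)) {
    pid <- sprintf("pt_%05d", i)
    with_seed(substream_seed(cfg$seed, paste0("patient_", i)), {
      s <- sample.int(7, 1, prob = cfg$stratum_weights)
      rapid <- runif(1) < cfg$rapid_fraction_per_stratum[s]
      lo <- strata$egfr_lo[s]
      hi <- if (is.finite(strata$egfr_hi[s])) strata$egfr_hi[s] else 115
      if (s == 7) lo <- 12
      baseline <- runif(1, lo, hi)
      slope <- if (rapid) {
        runif(1, cfg$slope_rapid_range[1], cfg$slope_rapid_range[2])
      } else {
        runif(1, cfg$slope_stable_range[1], cfg$slope_stable_range[2])
      }
      fu_mean <- if (rapid) cfg$followup_years_rapid else cfg$followup_years_stable
      followup <- max(0.5, rnorm(1, fu_mean, cfg$followup_sd))
      if (slope < 0) {
        # declining patients leave follow-up before eGFR reaches the floor
        # (clinically: kidney failure ends the observation window)
        followup <- max(0.5, min(followup, (baseline - 5) / (-slope)))
      }
      n_visits <- sample(seq.int(cfg$n_visits_range[1], cfg$n_visits_range[2]), 1)
      tr <- generate_trajectory(baseline, slope, n_visits,
                                cfg$visit_noise_sd, followup)

      shift <- function(name) if (rapid) cs[[name]][s] else 0
      age <- max(18, rnorm(1, 50.38 + shift("age"), 14))
      sex <- if (runif(1) < plogis(qlogis(0.456) + shift("sex_logit"))) "female" else "male"
      diabetes <- runif(1) < plogis(qlogis(0.678) + shift("diabetes_logit"))
      sbp <- rnorm(1, 127.96 + shift("sbp"), 15.4)
      dbp <- rnorm(1, 77.26 + shift("dbp"), 8.7)
      uae <- rlnorm(1, 3.38 + shift("log_uae"), 1.6)
      acr <- uae * rlnorm(1, 0, 0.3)

      # peptide profile
      row <- numeric(np)
      row[seq_len(nh)] <- rlnorm(nh, pep$mu[seq_len(nh)], cfg$housekeeping_log_sd)
      delta <- numeric(n_reg)
      p_det <- rep(cfg$detect_prob_background, n_reg)
      if (rapid && length(layout[[s]])) {
        ix <- layout[[s]]
        eff <- cfg$planted_effect_per_stratum[s] * pep$sign[ix]
        delta[ix] <- eff * log(2)
        if (cfg$effect_on_detection) {
          p_det[ix] <- plogis(qlogis(p_det[ix]) +
                                cfg$detection_effect_scale * eff)
        }
      }
      detected <- runif(n_reg) < p_det
      vals <- rlnorm(n_reg, pep$mu[nh + seq_len(n_reg)] + delta, cfg$amplitude_log_sd)
      row[nh + seq_len(n_reg)] <- ifelse(detected, vals, 0)
      amp[i, ] <- row

      clinical[[i]] <- data.frame(
        patient_id = pid, age = age, sex = sex, diabetes = diabetes,
        sbp = sbp, dbp = dbp, uae = uae, acr = acr,
        baseline_egfr = baseline, followup_years = followup,
        true_slope = slope, true_group = if (rapid) "rapid" else "stable",
        true_stratum = s, stringsAsFactors = FALSE
      )
      traj[[i]] <- data.frame(patient_id = pid, time = tr$time, egfr = tr$egfr)
    })
  }

  clinical <- do.call(rbind, clinical)
  rownames(clinical) <- NULL
  trajectories <- do.call(rbind, traj)
  rownames(trajectories) <- NULL

  truth <- list(
    planted_ids = planted_ids,
    planted_sign = setNames(pep$sign, reg_ids),
    peptide_mu = setNames(pep$mu, peptide_ids),
    amplitude_log_sd = cfg$amplitude_log_sd,
    detect_prob_background = cfg$detect_prob_background,
    planted_effect_per_stratum = cfg$planted_effect_per_stratum,
    effect_on_detection = cfg$effect_on_detection,
    detection_effect_scale = cfg$detection_effect_scale,
    seed = cfg$seed
  )

  list(
    matrix = peptide_matrix(amp, housekeeping_ids = hk_ids),
    clinical = clinical,
    trajectories = trajectories,
    truth = truth
  )
}
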