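#' Stratum layout of the emulated study population
#'
#' Patient counts per baseline-eGFR stratum in the cohort the generator
#' emulates: strata 1..7 cover eGFR >=80, 70-79, 60-69, 50-59, 40-49,
#' 30-39 and <30 ml/min/1.73 m^2. `rapid` and `stable` are the numbers of
#' rapid and non-rapid progressors per stratum (totals 342 and 1140 over
#' 1482 patients).
#'
#' @return data.frame with columns stratum, egfr_lo, egfr_hi, rapid,
#'   stable, total
#' @export
#' @examples
#' reference_strata()
reference_strata <- function() {
  data.frame(
    stratum = 1:7,
    egfr_lo = c(80, 70, 60, 50, 40, 30, 0),
    egfr_hi = c(Inf, 80, 70, 60, 50, 40, 30),
    rapid   = c(129, 64, 25, 16, 26, 44, 38),
    stable  = c(350, 317, 236, 110, 41, 36, 50),
    total   = c(479, 381, 261, 126, 67, 80, 88)
  )
}

#' Configuration for the synthetic cohort generator
#'
#' Default values emulate the structure of the study population the method
#' was developed on: 1482 patients spread over 7 baseline-eGFR strata with
#' stratum-specific rapid-progressor fractions, covariate shifts between
#' outcome groups (diabetes prevalence, age, systolic pressure, albuminuria),
#' roughly 5 eGFR visits over about 3 years of follow-up, and zero-inflated
#' log-normal peptide amplitudes normalized against 29 stable housekeeping
#' peptides.
#'
#' @param n_patients cohort size.
#' @param n_peptides total number of peptides including housekeeping.
#' @param n_housekeeping number of always-detected, low-variance
#'   housekeeping peptides used for normalization.
#' @param stratum_weights probabilities of the 7 baseline-eGFR strata
#'   (must sum to 1).
#' @param rapid_fraction_per_stratum probability of being a rapid progressor
#'   in each stratum.
#' @param n_planted_per_stratum number of truly differential peptides planted
#'   per stratum.
#' @param planted_log2_effect log2 fold change of planted peptide amplitudes
#'   between rapid and non-rapid progressors (sign drawn per peptide).
#' @param planted_effect_per_stratum optional length-7 vector of per-stratum
#'   log2 effects overriding `planted_log2_effect`; used to design cohorts in
#'   which peptide signal strength varies across strata.
#' @param planted_overlap fraction of planted peptides shared between
#'   adjacent strata (sliding-window construction), so that classifiers
#'   transfer best to neighbouring strata; 1 makes all strata share a
#'   single planted set.
#' @param effect_on_detection if TRUE the planted effect also shifts the
#'   detection probability (on the logit scale, scaled by
#'   `detection_effect_scale`), so that detection-frequency differences carry
#'   part of the signal.
#' @param detection_effect_scale logit shift per unit log2 effect.
#' @param detect_prob_background detection probability of non-housekeeping
#'   peptides in the absence of a planted effect, in (0, 1].
#' @param amplitude_log_mean,amplitude_log_sd natural-log mean and sd of
#'   detected peptide amplitudes (log-normal model).
#' @param peptide_mean_sd between-peptide sd of the baseline log-mean.
#' @param housekeeping_log_sd log-sd of housekeeping amplitudes (small, these
#'   peptides are stable by construction).
#' @param n_visits_range integer pair; per-patient visit count is drawn
#'   uniformly from this range (default 2..8, mean 5).
#' @param followup_years_rapid,followup_years_stable mean follow-up (years)
#'   by outcome group; rapid progressors are followed for less time.
#' @param followup_sd sd of follow-up duration (truncated at 0.5 years).
#' @param visit_noise_sd measurement noise of a single eGFR visit
#'   (ml/min/1.73 m^2).
#' @param slope_rapid_range,slope_stable_range uniform ranges for the true
#'   eGFR slope (ml/min/1.73 m^2 per year) of rapid and stable patients.
#'   The rapid range must lie entirely at or below -5 and the stable range
#'   within [-1.5, +5].
#' @param covariate_shift named list of offsets applied to rapid progressors:
#'   `age` (years), `sbp`, `dbp` (mmHg), `diabetes_logit`, `sex_logit`
#'   (logit shifts), `log_uae` (shift of log urinary albumin excretion).
#'   Each entry may be a scalar or a length-7 per-stratum vector.
#' @param seed master seed; every random draw in the generator derives
#'   from it through named substreams.
#' @return an object of class `cohort_config` (a validated list).
#' @export
#' @examples
#' cfg <- cohort_config(n_patients = 200, n_peptides = 100, seed = 1)
#' cfg$rapid_fraction_per_stratum
cohort_config <- function(n_patients = 1482,
                          n_peptides = 500,
                          n_housekeeping = 29,
                          stratum_weights = reference_strata()$total / 1482,
                          rapid_fraction_per_stratum =
                            reference_strata()$rapid / reference_strata()$total,
                          n_planted_per_stratum = 15,
                          planted_log2_effect = 1.0,
                          planted_effect_per_stratum = NULL,
                          planted_overlap = 0.5,
                          effect_on_detection = TRUE,
                          detection_effect_scale = 0.5,
                          detect_prob_background = 0.7,
                          amplitude_log_mean = 5,
                          amplitude_log_sd = 1,
                          peptide_mean_sd = 0.75,
                          housekeeping_log_sd = 0.2,
                          n_visits_range = c(2L, 8L),
                          followup_years_rapid = 2.48,
                          followup_years_stable = 3.46,
                          followup_sd = 1.1,
                          visit_noise_sd = 2.5,
                          slope_rapid_range = c(-12, -5),
                          slope_stable_range = c(-1.5, 5),
                          covariate_shift = list(
                            age = 5.21, sbp = 5.73, dbp = -0.88,
                            diabetes_logit = 2.66, sex_logit = -0.08,
                            log_uae = 1.85
                          ),
                          seed = 1L) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    n_peptides = as.integer(n_peptides),
    n_housekeeping = as.integer(n_housekeeping),
    stratum_weights = as.numeric(stratum_weights),
    rapid_fraction_per_stratum = as.numeric(rapid_fraction_per_stratum),
    n_planted_per_stratum = as.integer(n_planted_per_stratum),
    planted_log2_effect = as.numeric(planted_log2_effect),
    planted_effect_per_stratum =
      if (is.null(planted_effect_per_stratum)) {
        rep(as.numeric(planted_log2_effect), 7)
      } else {
        as.numeric(planted_effect_per_stratum)
      },
    planted_overlap = as.numeric(planted_overlap),
    effect_on_detection = isTRUE(effect_on_detection),
    detection_effect_scale = as.numeric(detection_effect_scale),
    detect_prob_background = as.numeric(detect_prob_background),
    amplitude_log_mean = as.numeric(amplitude_log_mean),
    amplitude_log_sd = as.numeric(amplitude_log_sd),
    peptide_mean_sd = as.numeric(peptide_mean_sd),
    housekeeping_log_sd = as.numeric(housekeeping_log_sd),
    n_visits_range = as.integer(n_visits_range),
    followup_years_rapid = as.numeric(followup_years_rapid),
    followup_years_stable = as.numeric(followup_years_stable),
    followup_sd = as.numeric(followup_sd),
    visit_noise_sd = as.numeric(visit_noise_sd),
    slope_rapid_range = as.numeric(slope_rapid_range),
    slope_stable_range = as.numeric(slope_stable_range),
    covariate_shift = covariate_shift,
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

#' Validate a cohort configuration
#'
#' Checks the structural invariants of the generator configuration: stratum
#' weights form a probability vector over 7 strata, the rapid slope range
#' lies entirely at or below -5 and the stable range within [-1.5, +5],
#' housekeeping peptides are fewer than total peptides, and the planted
#' peptide windows fit into the non-housekeeping pool (so planted ids are
#' always disjoint from housekeeping ids).
#'
#' @param cfg a `cohort_config`
#' @return the config, invisibly; errors on violation.
#' @export
validate_cohort_config <- function(cfg) {
  w <- cfg$stratum_weights
  if (length(w) != 7 || any(!is_prob(w)) || abs(sum(w) - 1) > 1e-8) {
    stopf("stratum_weights must be 7 probabilities summing to 1")
  }
  rf <- cfg$rapid_fraction_per_stratum
  if (length(rf) != 7 || any(!is_prob(rf))) {
    stopf("rapid_fraction_per_stratum must be 7 probabilities")
  }
  if (!is_count(cfg$n_patients) || cfg$n_patients < 1) {
    stopf("n_patients must be a positive count")
  }
  if (cfg$n_housekeeping >= cfg$n_peptides) {
    stopf("n_housekeeping must be smaller than n_peptides")
  }
  if (!(cfg$detect_prob_background > 0 && cfg$detect_prob_background <= 1)) {
    stopf("detect_prob_background must be in (0, 1]")
  }
  if (cfg$amplitude_log_sd <= 0 || cfg$visit_noise_sd < 0) {
    stopf("amplitude_log_sd must be positive and visit_noise_sd non-negative")
  }
  if (length(cfg$n_visits_range) != 2 || cfg$n_visits_range[1] < 2 ||
      cfg$n_visits_range[2] < cfg$n_visits_range[1]) {
    stopf("n_visits_range must be an increasing integer pair with minimum >= 2")
  }
  if (max(cfg$slope_rapid_range) > -5) {
    stopf("slope_rapid_range must lie entirely at or below -5")
  }
  if (min(cfg$slope_stable_range) < -1.5 || max(cfg$slope_stable_range) > 5) {
    stopf("slope_stable_range must lie within [-1.5, +5]")
  }
  if (length(cfg$planted_effect_per_stratum) != 7) {
    stopf("planted_effect_per_stratum must have length 7")
  }
  if (!(cfg$planted_overlap >= 0 && cfg$planted_overlap <= 1)) {
    stopf("planted_overlap must be in [0, 1]")
  }
  layout <- planted_layout(cfg)
  pool <- cfg$n_peptides - cfg$n_housekeeping
  if (cfg$n_planted_per_stratum > 0 && max(unlist(layout)) > pool) {
    stopf(
      "planted peptides (7 strata x %d, overlap %.2f) exceed the %d non-housekeeping peptides",
      cfg$n_planted_per_stratum, cfg$planted_overlap, pool
    )
  }
  invisible(cfg)
}

# Sliding-window indices (into the non-housekeeping pool) of the peptides
# planted for each stratum; adjacent strata share ~planted_overlap of them.
# overlap 1 means every stratum shares one planted set.
planted_layout <- function(cfg) {
  k <- cfg$n_planted_per_stratum
  if (k == 0) {
    return(rep(list(integer(0)), 7))
  }
  step <- as.integer(round(k * (1 - cfg$planted_overlap)))
  lapply(1:7, function(s) seq.int((s - 1L) * step + 1L, (s - 1L) * step + k))
}

#' Read a cohort configuration from YAML or JSON
#'
#' Only keys present in the file override `cohort_config()` defaults.
#'
#' @param path file path ending in .yaml/.yml or .json
#' @return a `cohort_config`
#' @export
read_cohort_config <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(cohort_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stopf("unknown config fields: %s", paste(unknown, collapse = ", "))
  do.call(cohort_config, vals)
}
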