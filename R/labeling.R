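#' Ordinary least-squares eGFR slope of a trajectory
#'
#' Fits eGFR on visit time (years) by unweighted least squares and returns
#' the slope in ml/min/1.73 m^2 per year. Requires at least two visits at
#' distinct times.
#'
#' @param times visit times in years
#' @param egfr eGFR values, same length
#' @return the OLS slope
#' @export
#' @examples
#' estimate_slope(c(0, 1, 2), c(90, 85, 80)) # -5
estimate_slope <- function(times, egfr) {
  if (is.data.frame(times)) {
    egfr <- times$egfr
    times <- times$time
  }
  if (length(times) != length(egfr)) stopf("times and egfr lengths differ")
  if (length(times) < 2) stopf("slope needs at least two visits")
  if (!all(is.finite(times)) || !all(is.finite(egfr))) stopf("non-finite input")
  ct <- times - mean(times)
  denom <- sum(ct^2)
  if (denom == 0) stopf("all visit times are equal")
  sum(ct * (egfr - mean(egfr))) / denom
}

#' Classify a patient's eGFR slope into a progression group
#'
#' Rapid progression is a sustained eGFR decline of at least 5
#' ml/min/1.73 m^2 per year (KDIGO definition); non-rapid progressors have a
#' slope between -1.5 and +5. Slopes in the grey zone (-5, -1.5) and
#' apparent increases above +5 are excluded from case-control analysis.
#' Thresholds are configurable; boundary values go to rapid (-5) and stable
#' (-1.5 and +5) respectively.
#'
#' @param slope eGFR slope(s), ml/min/1.73 m^2 per year (vectorized)
#' @param rapid_max slope at or below which a patient is a rapid progressor
#' @param stable_min,stable_max closed interval of stable slopes
#' @return character vector in {"rapid", "stable", "excluded_grey_zone",
#'   "excluded_rising"}
#' @export
#' @examples
#' classify_progression(c(-6, -5, -3, 0, 5, 7))
classify_progression <- function(slope, rapid_max = -5,
                                 stable_min = -1.5, stable_max = 5) {
  if (!all(is.finite(slope))) stopf("slope must be finite")
  ifelse(slope <= rapid_max, "rapid",
    ifelse(slope < stable_min, "excluded_grey_zone",
      ifelse(slope <= stable_max, "stable", "excluded_rising")
    )
  )
}

#' Assign the baseline-eGFR stratum
#'
#' Seven half-open strata: [80, Inf), [70, 80), [60, 70), [50, 60),
#' [40, 50), [30, 40), (0, 30). Boundary values go to the higher stratum
#' (eGFR 80 is stratum 1).
#'
#' @param baseline_egfr positive eGFR value(s), ml/min/1.73 m^2 (vectorized)
#' @return integer stratum id(s) in 1..7
#' @export
#' @examples
#' assign_stratum(c(95, 80, 75, 29.9))
assign_stratum <- function(baseline_egfr) {
  if (any(!is.finite(baseline_egfr)) || any(baseline_egfr <= 0)) {
    stopf("baseline_egfr must be positive and finite")
  }
  7L - findInterval(baseline_egfr, c(30, 40, 50, 60, 70, 80))
}

#' Label a cohort: slopes, progression groups and strata
#'
#' Applies [estimate_slope()], [classify_progression()] and
#' [assign_stratum()] to every patient. The baseline eGFR used for
#' stratification is the clinical table's `baseline_egfr` column.
#'
#' @param clinical clinical data.frame with `patient_id` and `baseline_egfr`
#' @param trajectories long data.frame (patient_id, time, egfr)
#' @param ... threshold overrides passed to [classify_progression()]
#' @return data.frame (patient_id, slope, label, stratum)
#' @export
label_cohort <- function(clinical, trajectories, ...) {
  ids <- clinical$patient_id
  traj_split <- split(trajectories[, c("time", "egfr")], trajectories$patient_id)
  missing <- setdiff(ids, names(traj_split))
  if (length(missing)) {
    stopf("patients without trajectory: %s", paste(head(missing, 5), collapse = ", "))
  }
  slopes <- vapply(ids, function(id) estimate_slope(traj_split[[id]]), numeric(1))
  data.frame(
    patient_id = ids,
    slope = unname(slopes),
    label = classify_progression(unname(slopes), ...),
    stratum = assign_stratum(clinical$baseline_egfr),
    stringsAsFactors = FALSE
  )
}
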