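#' 4-variable Kidney Failure Risk Equation
#'
#' Estimated risk of progression to end-stage renal disease within 2 and 5
#' years from age, sex, eGFR and urinary albumin-to-creatinine ratio, using
#' the published 4-variable coefficients: risk = 1 - S0^exp(lp) with
#' lp = -0.2201 (age/10 - 7.036) + 0.2467 (male - 0.5642)
#'     - 0.5567 (eGFR/5 - 7.222) + 0.4510 (ln ACR - 5.137).
#' Baseline survivals: North American calibration 0.9832 (2 y) and 0.9365
#' (5 y); non-North-American recalibration 0.9878 and 0.9570 (the default
#' here, appropriate for predominantly European cohorts). ACR values of 0
#' are floored at 1 mg/g before the log. Vectorized and deterministic.
#'
#' @param age years (> 0)
#' @param sex "female"/"male" (or logical male indicator)
#' @param egfr eGFR, ml/min/1.73 m^2 (> 0)
#' @param acr urinary albumin-to-creatinine ratio, mg/g (>= 0; 0 floored
#'   at 1)
#' @param calibration "non_north_american" (default) or "north_american"
#' @return data.frame(risk_2yr, risk_5yr), risks in [0, 1]
#' @export
#' @examples
#' kfre_risk(age = 60, sex = "male", egfr = 25, acr = 300)
kfre_risk <- function(age, sex, egfr, acr,
                      calibration = c("non_north_american", "north_american")) {
  calibration <- match.arg(calibration)
  if (any(age <= 0) || any(egfr <= 0)) stopf("age and egfr must be positive")
  if (any(acr < 0)) stopf("acr must be non-negative")
  male <- if (is.logical(sex)) sex else tolower(as.character(sex)) == "male"
  acr <- pmax(acr, 1)
  lp <- -0.2201 * (age / 10 - 7.036) +
    0.2467 * (as.numeric(male) - 0.5642) -
    0.5567 * (egfr / 5 - 7.222) +
    0.4510 * (log(acr) - 5.137)
  s0 <- switch(calibration,
    north_american = c(two = 0.9832, five = 0.9365),
    non_north_american = c(two = 0.9878, five = 0.9570)
  )
  data.frame(
    risk_2yr = 1 - s0[["two"]]^exp(lp),
    risk_5yr = 1 - s0[["five"]]^exp(lp)
  )
}

#' CKD-EPI 2009 estimated GFR
#'
#' Creatinine-based piecewise power equation:
#' eGFR = 141 min(Scr/k, 1)^a max(Scr/k, 1)^-1.209 0.993^age
#' [x 1.018 if female] [x 1.159 if Black], with k = 0.7 (female) / 0.9
#' (male) and a = -0.329 / -0.411. The race coefficient is off by default.
#'
#' @param serum_creatinine mg/dL (> 0)
#' @param age years (> 0)
#' @param sex "female"/"male"
#' @param black apply the 1.159 coefficient (default FALSE)
#' @return eGFR in ml/min/1.73 m^2
#' @export
#' @examples
#' ckd_epi_egfr(1.0, age = 50, sex = "female")
ckd_epi_egfr <- function(serum_creatinine, age, sex, black = FALSE) {
  if (any(serum_creatinine <= 0) || any(age <= 0)) {
    stopf("serum creatinine and age must be positive")
  }
  female <- tolower(as.character(sex)) == "female"
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.329, -0.411)
  r <- serum_creatinine / kappa
  egfr <- 141 * pmin(r, 1)^alpha * pmax(r, 1)^-1.209 * 0.993^age
  egfr <- egfr * ifelse(female, 1.018, 1)
  if (isTRUE(black)) egfr <- egfr * 1.159
  unname(egfr)
}

#' Cox proportional-hazards association of a classifier score with rapid
#' progression
#'
#' Fits a Cox model (Efron tie handling) of time-to-diagnosis-as-rapid-
#' progressor on the classifier score, optionally adjusted for covariates.
#' The hazard ratio is reported per 1 SD of the score when `standardize`
#' (the scale is always recorded in the output). Collinear covariates are
#' flagged, not silently dropped.
#'
#' @param scores numeric classifier scores
#' @param followup_years follow-up time per patient (> 0)
#' @param event logical/0-1: was the patient diagnosed a rapid progressor
#' @param covariates optional data.frame of adjustment covariates
#' @param standardize report the HR per 1 SD of score (default TRUE)
#' @return list(hazard_ratio, ci_low, ci_high, p_value, scale, n_events,
#'   coefficients, collinear)
#' @export
cox_association <- function(scores, followup_years, event,
                            covariates = NULL, standardize = TRUE) {
  event <- as.integer(as_case(event))
  if (sum(event) < 1) stopf("at least one event is required")
  if (any(followup_years < 0)) stopf("negative follow-up time")
  sc <- as.numeric(scores)
  scale_lab <- "per unit"
  if (standardize) {
    s <- sd(sc)
    if (s == 0) stopf("score has zero variance")
    sc <- sc / s
    scale_lab <- "per 1 SD"
  }
  df <- data.frame(time = followup_years, event = event, score = sc)
  if (!is.null(covariates)) df <- cbind(df, covariates)
  fit <- survival::coxph(survival::Surv(time, event) ~ .,
                         data = df, ties = "efron")
  cf <- summary(fit)$coefficients
  ci <- summary(fit)$conf.int
  if (any(is.na(coef(fit)))) {
    collinear <- names(coef(fit))[is.na(coef(fit))]
    warning(sprintf("collinear covariates: %s", paste(collinear, collapse = ", ")),
            call. = FALSE)
  } else {
    collinear <- character(0)
  }
  list(
    hazard_ratio = unname(ci["score", "exp(coef)"]),
    ci_low = unname(ci["score", "lower .95"]),
    ci_high = unname(ci["score", "upper .95"]),
    p_value = unname(cf["score", "Pr(>|z|)"]),
    scale = scale_lab,
    n_events = sum(event),
    coefficients = coef(fit),
    collinear = collinear
  )
}
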