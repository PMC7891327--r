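# Logistic recalibration and model extension. Fits go through glm (IRLS,
# binomial family) with a tight convergence tolerance; perfect separation and
# degenerate predictors are surfaced as errors rather than silent divergence.

.fit_logistic <- function(formula, data) {
  # divergence is diagnosed explicitly below; glm's own 0/1-fitted warning
  # would only duplicate it
  fit <- suppressWarnings(
    stats::glm(formula, data = data, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  )
  if (!fit$converged || any(abs(stats::coef(fit)) > 40)) {
    stop("logistic fit diverged: perfect (or quasi-perfect) separation suspected")
  }
  fit
}

#' Recalibrate a published risk model on a cohort
#'
#' Fits outcome ~ linear predictor by maximum-likelihood logistic regression,
#' yielding an updated calibration intercept and slope. A model that already
#' fits the cohort perfectly returns slope 1 and intercept 0 up to
#' convergence tolerance.
#'
#' @param model a [model_spec()].
#' @param cohort complete cohort `data.frame` with both outcome classes.
#' @return list of class `recalibration_result`: `calibration_intercept`,
#'   `calibration_slope`, their variance-covariance matrix `vcov`,
#'   `log_likelihood`, `n`.
#' @export
recalibrate <- function(model, cohort) {
  lp <- linear_predictor(model, cohort)
  y <- cohort$gdm
  if (length(unique(y)) < 2L) stop("outcome must contain both classes")
  if (stats::sd(lp) < 1e-12) stop("degenerate constant linear predictor")
  fit <- .fit_logistic(y ~ lp, data = data.frame(y = y, lp = lp))
  cf <- stats::coef(fit)
  structure(list(calibration_intercept = unname(cf[1L]),
                 calibration_slope = unname(cf[2L]),
                 vcov = stats::vcov(fit),
                 log_likelihood = as.numeric(stats::logLik(fit)),
                 n = length(y)),
            class = "recalibration_result")
}

#' Extend a recalibrated model with ln(glucose)
#'
#' Jointly refits outcome ~ {recalibrated linear predictor, natural-log
#' first-trimester random venous glucose}; glucose enters on the log scale
#' because of its right-skewed distribution. Both coefficients are
#' re-estimated, so the extended in-sample log-likelihood can never fall
#' below the recalibrated one.
#'
#' @param recal a `recalibration_result` from [recalibrate()].
#' @param model the underlying [model_spec()].
#' @param cohort complete cohort with positive `glucose_mmol_l`.
#' @return list of class `extended_model`: `intercept`, `lp_coefficient`,
#'   `glucose_coefficient`, `vcov`, `log_likelihood`, `n`.
#' @export
extend_with_glucose <- function(recal, model, cohort) {
  stopifnot(inherits(recal, "recalibration_result"))
  if (any(cohort$glucose_mmol_l <= 0)) {
    stop("glucose_mmol_l must be strictly positive for the log transform")
  }
  lp_recal <- recal$calibration_intercept +
    recal$calibration_slope * linear_predictor(model, cohort)
  d <- data.frame(y = cohort$gdm, lp = lp_recal,
                  ln_glucose = log(cohort$glucose_mmol_l))
  fit <- .fit_logistic(y ~ lp + ln_glucose, data = d)
  cf <- stats::coef(fit)
  structure(list(intercept = unname(cf[1L]), lp_coefficient = unname(cf[2L]),
                 glucose_coefficient = unname(cf[3L]),
                 vcov = stats::vcov(fit),
                 log_likelihood = as.numeric(stats::logLik(fit)),
                 n = nrow(cohort)),
            class = "extended_model")
}

#' Likelihood-ratio chi-square test for nested logistic models
#'
#' @param loglik_nested log-likelihood of the nested model at its MLE.
#' @param loglik_extended log-likelihood of the extending model at its MLE.
#' @param df difference in number of parameters (>= 1).
#' @return list of class `lr_test_result`: `chi_square`, `df`, `p_value`.
#' @export
lr_test <- function(loglik_nested, loglik_extended, df = 1L) {
  if (df < 1) stop("df must be a positive integer")
  if (loglik_extended < loglik_nested - 1e-6) {
    stop("extended log-likelihood below nested: models are not nested MLE fits")
  }
  chi <- max(0, 2 * (loglik_extended - loglik_nested))
  structure(list(chi_square = chi, df = as.integer(df),
                 p_value = stats::pchisq(chi, df, lower.tail = FALSE)),
            class = "lr_test_result")
}

# score a cohort with pooled recalibration coefficients
.recalibrated_risk <- function(model, cohort, intercept, slope) {
  predicted_risk(intercept + slope * linear_predictor(model, cohort))
}

.extended_risk <- function(model, cohort, recal_intercept, recal_slope,
                           intercept, lp_coefficient, glucose_coefficient) {
  lp_recal <- recal_intercept + recal_slope * linear_predictor(model, cohort)
  predicted_risk(intercept + lp_coefficient * lp_recal +
                   glucose_coefficient * log(cohort$glucose_mmol_l))
}
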