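#' Default covariate distribution settings
#'
#' Marginals matched to the published cohort description of a Dutch low-risk
#' obstetric population (n = 3723): age normal mean 30.8 sd 4.2 years; SBP
#' normal mean 115 sd 12 mmHg; pre-pregnancy BMI log-normal, median 23.2,
#' IQR 21.1-26.2 kg/m^2; first-trimester random venous glucose log-normal,
#' median 4.7, IQR 4.4-5.1 mmol/l; 91.0% Caucasian; 44.5% nulliparous; 14.6%
#' family history of diabetes; 1.6% prior GDM and 6.2% prior macrosomia
#' (overall rates, realised only among parous women); 9.0% smoking. The
#' log-normal shapes take meanlog from the median and sdlog from the quartile
#' ratio. `copula_rho` is the common latent Gaussian-copula correlation
#' between age, BMI, SBP and glucose.
#'
#' @return named list of per-covariate settings.
#' @export
default_covariate_params <- function() {
  list(
    age = list(mean = 30.8, sd = 4.2),
    sbp = list(mean = 115, sd = 12),
    bmi = list(median = 23.2, q25 = 21.1, q75 = 26.2),
    glucose = list(median = 4.7, q25 = 4.4, q75 = 5.1),
    height = list(mean = 168, sd = 6.5),
    ethnicity = c(caucasian = 0.910, african = 0.008, asian = 0.014,
                  mixed = 0.021, other = 0.047),
    education = c(low = 270, medium = 1273, high = 2180) / 3723,
    conception = c(spontaneous = 3429, ovulation_drugs = 99, ivf = 110) / 3638,
    parity = c("0" = 0.445, "1" = 0.370, "2" = 0.140, "3" = 0.035, "4" = 0.010),
    smoking = 0.090,
    family_history_dm = 0.146,
    history_gdm = 0.016,
    history_macrosomia = 0.062,
    copula_rho = 0.25
  )
}

#' Default true outcome mechanism for synthetic cohorts
#'
#' A logistic risk equation over BMI, age, ln(glucose), history of GDM,
#' family history of diabetes and non-western ethnicity, with effect
#' directions and magnitudes chosen so the simulated cohort reproduces the
#' reported discrimination landscape (glucose alone discriminating at roughly
#' c 0.68, clinical predictors adding to roughly c 0.7-0.8 overall). The
#' intercept is nominal: `generate_cohort()` re-tunes it by bisection to the
#' configured target prevalence.
#'
#' @return a [model_spec()].
#' @export
default_outcome_model <- function() {
  model_spec("custom", intercept = -25, terms = list(
    list(predictor = "bmi", transform = "identity", coefficient = 0.18),
    list(predictor = "age_years", transform = "identity", coefficient = 0.05),
    list(predictor = "glucose_mmol_l", transform = "natural_log", coefficient = 6.0),
    list(predictor = "history_gdm", transform = "identity", coefficient = 2.2),
    list(predictor = "family_history_dm", transform = "identity", coefficient = 0.9),
    list(predictor = "ethnicity", transform = "indicator", level = "asian",
         coefficient = 1.2),
    list(predictor = "ethnicity", transform = "indicator", level = "other",
         coefficient = 0.6)
  ))
}

#' Configuration for the synthetic cohort generator
#'
#' @param n_subjects number of pregnancies to simulate.
#' @param covariate_params per-covariate settings, see
#'   [default_covariate_params()].
#' @param outcome_model a [model_spec()] used as the true risk mechanism.
#' @param target_prevalence outcome prevalence in (0,1) the intercept is
#'   tuned to, or `NULL` to use the outcome model's intercept as-is.
#' @param seed integer RNG seed.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_subjects = 3723,
                             covariate_params = default_covariate_params(),
                             outcome_model = default_outcome_model(),
                             target_prevalence = 0.049,
                             seed = 1L) {
  if (!is.numeric(n_subjects) || n_subjects < 1) {
    stop("n_subjects must be a positive integer")
  }
  p <- covariate_params
  for (nm in c("age", "sbp", "height")) {
    if (p[[nm]]$sd <= 0) stop("covariate_params$", nm, "$sd must be positive")
  }
  for (nm in c("bmi", "glucose")) {
    q <- p[[nm]]
    if (!(q$q25 < q$median && q$median < q$q75) || q$q25 <= 0) {
      stop("covariate_params$", nm, " quartiles must satisfy 0 < q25 < median < q75")
    }
  }
  for (nm in c("ethnicity", "education", "conception", "parity")) {
    pr <- p[[nm]]
    if (any(pr < 0) || any(pr > 1) || abs(sum(pr) - 1) > 1e-9) {
      stop("covariate_params$", nm, " probabilities must lie in [0,1] and sum to 1")
    }
  }
  for (nm in c("smoking", "family_history_dm", "history_gdm", "history_macrosomia")) {
    if (p[[nm]] < 0 || p[[nm]] > 1) stop("covariate_params$", nm, " must lie in [0,1]")
  }
  if (abs(p$copula_rho) >= 1) stop("covariate_params$copula_rho must lie in (-1,1)")
  if (!is.null(target_prevalence) &&
      (target_prevalence <= 0 || target_prevalence >= 1)) {
    stop("target_prevalence must lie in (0,1)")
  }
  stopifnot(inherits(outcome_model, "model_spec"))
  structure(list(n_subjects = as.integer(n_subjects), covariate_params = p,
                 outcome_model = outcome_model,
                 target_prevalence = target_prevalence, seed = as.integer(seed)),
            class = "generator_config")
}

.lognormal_pars <- function(q) {
  # meanlog from the median; sdlog from the quartile ratio
  list(meanlog = log(q$median),
       sdlog = log(q$q75 / q$q25) / (2 * stats::qnorm(0.75)))
}

#' Generate a synthetic maternal cohort
#'
#' Draws age, BMI, SBP and glucose from a Gaussian copula with the configured
#' marginals, height from an independent normal, and back-solves weight so
#' that BMI = weight / (height/100)^2 holds exactly. Categorical and binary
#' covariates are drawn independently; prior-GDM and prior-macrosomia rates
#' are rescaled among parous women so the overall marginal matches the
#' configured rate while parity 0 implies no obstetric history. The GDM
#' outcome is Bernoulli with probability `plogis(lp)` from the configured
#' true outcome model, whose intercept is tuned by bisection on the realised
#' covariates when `target_prevalence` is set.
#'
#' @param config a [generator_config()].
#' @return `data.frame` with the cohort schema columns (see README); binary
#'   fields coded 0/1.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  p <- config$covariate_params
  n <- config$n_subjects
  set.seed(config$seed)

  # latent copula: age, bmi, sbp, glucose
  rho <- p$copula_rho
  R <- matrix(rho, 4, 4); diag(R) <- 1
  z <- matrix(stats::rnorm(n * 4L), n, 4L) %*% chol(R)
  u <- stats::pnorm(z)

  bmi_par <- .lognormal_pars(p$bmi)
  glu_par <- .lognormal_pars(p$glucose)
  age <- stats::qnorm(u[, 1L], p$age$mean, p$age$sd)
  bmi <- stats::qlnorm(u[, 2L], bmi_par$meanlog, bmi_par$sdlog)
  sbp <- stats::qnorm(u[, 3L], p$sbp$mean, p$sbp$sd)
  glucose <- stats::qlnorm(u[, 4L], glu_par$meanlog, glu_par$sdlog)

  height <- stats::rnorm(n, p$height$mean, p$height$sd)
  weight <- bmi * (height / 100)^2

  ethnicity <- sample(names(p$ethnicity), n, replace = TRUE, prob = p$ethnicity)
  education <- sample(names(p$education), n, replace = TRUE, prob = p$education)
  conception <- sample(names(p$conception), n, replace = TRUE, prob = p$conception)
  parity <- as.integer(sample(names(p$parity), n, replace = TRUE, prob = p$parity))
  smoking <- stats::rbinom(n, 1L, p$smoking)
  family_history_dm <- stats::rbinom(n, 1L, p$family_history_dm)

  # obstetric history only possible for parous women; rescale so the overall
  # marginal hits the configured rate
  p_parous <- 1 - unname(p$parity["0"])
  hist_gdm_rate <- min(1, p$history_gdm / p_parous)
  hist_mac_rate <- min(1, p$history_macrosomia / p_parous)
  parous <- parity > 0L
  history_gdm <- integer(n)
  history_macrosomia <- integer(n)
  history_gdm[parous] <- stats::rbinom(sum(parous), 1L, hist_gdm_rate)
  history_macrosomia[parous] <- stats::rbinom(sum(parous), 1L, hist_mac_rate)

  cohort <- data.frame(
    age_years = age, height_cm = height, weight_kg = weight, bmi = bmi,
    sbp_mmhg = sbp, glucose_mmol_l = glucose, ethnicity = ethnicity,
    education = education, smoking = smoking,
    family_history_dm = family_history_dm, conception = conception,
    parity = parity, history_gdm = history_gdm,
    history_macrosomia = history_macrosomia, gdm = 0L,
    stringsAsFactors = FALSE
  )

  lp <- linear_predictor(config$outcome_model, cohort)
  if (!is.null(config$target_prevalence)) {
    slope_part <- lp - config$outcome_model$intercept
    f <- function(a) mean(stats::plogis(a + slope_part)) - config$target_prevalence
    a <- stats::uniroot(f, c(-60, 20), tol = 1e-10)$root
    lp <- a + slope_part
  }
  cohort$gdm <- stats::rbinom(n, 1L, stats::plogis(lp))
  attr(cohort, "true_lp") <- lp
  cohort
}

#' Configuration for injecting missing values
#'
#' @param mechanism `"MCAR"` (completely at random) or `"MAR"` (probability
#'   follows a logistic function of an always-observed covariate).
#' @param rates named list/vector of per-column missingness rates in `[0,1)`.
#'   The outcome `gdm` may never be made missing.
#' @param mar_dependence for MAR: `list(covariate =, weight =)`; the
#'   missingness logit is `a + weight * covariate`, with `a` solved so the
#'   marginal rate matches the configured rate.
#' @param seed integer RNG seed.
#' @return object of class `missingness_config`.
#' @export
missingness_config <- function(mechanism = c("MCAR", "MAR"),
                               rates = list(glucose_mmol_l = 0.10,
                                            sbp_mmhg = 0.05,
                                            height_cm = 0.02,
                                            weight_kg = 0.02,
                                            education = 0.03,
                                            smoking = 0.01),
                               mar_dependence = NULL,
                               seed = 1L) {
  mechanism <- match.arg(mechanism)
  rates <- unlist(rates)
  if ("gdm" %in% names(rates)) stop("the outcome 'gdm' may never be set missing")
  bad <- setdiff(names(rates), .cohort_columns)
  if (length(bad)) stop("unknown columns in rates: ", paste(bad, collapse = ", "))
  if (any(rates < 0) || any(rates >= 1)) stop("missing rates must lie in [0,1)")
  if (mechanism == "MAR") {
    if (is.null(mar_dependence$covariate) || is.null(mar_dependence$weight)) {
      stop("MAR requires mar_dependence = list(covariate =, weight =)")
    }
    dep <- mar_dependence$covariate
    if (!dep %in% .cohort_columns) stop("unknown MAR dependence covariate: ", dep)
    if (dep %in% names(rates) && rates[[dep]] > 0) {
      stop("MAR dependence covariate '", dep, "' must not itself be set missing")
    }
  }
  structure(list(mechanism = mechanism, rates = rates,
                 mar_dependence = mar_dependence, seed = as.integer(seed)),
            class = "missingness_config")
}

#' Replace values by NA under a configured missingness mechanism
#'
#' @param cohort complete cohort `data.frame`.
#' @param config a [missingness_config()].
#' @return the cohort with `NA`s injected; `gdm` untouched.
#' @export
apply_missingness <- function(cohort, config) {
  stopifnot(is.data.frame(cohort), inherits(config, "missingness_config"))
  if (anyNA(cohort)) stop("apply_missingness expects a complete cohort")
  set.seed(config$seed)
  out <- cohort
  for (col in names(config$rates)) {
    rate <- config$rates[[col]]
    if (rate == 0) next
    n <- nrow(out)
    if (config$mechanism == "MCAR") {
      miss <- stats::runif(n) < rate
    } else {
      x <- as.numeric(cohort[[config$mar_dependence$covariate]])
      w <- config$mar_dependence$weight
      f <- function(a) mean(stats::plogis(a + w * x)) - rate
      a <- stats::uniroot(f, c(-50 - abs(w) * max(abs(x)), 50 + abs(w) * max(abs(x))),
                          tol = 1e-10)$root
      miss <- stats::runif(n) < stats::plogis(a + w * x)
    }
    out[[col]][miss] <- NA
  }
  out
}
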