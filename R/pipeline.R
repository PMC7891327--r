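# End-to-end orchestration: simulate (or read) -> inject missingness ->
# impute -> recalibrate & extend -> evaluate -> decision curves & scenarios.

#' Analysis configuration
#'
#' @param generator a [generator_config()] for a synthetic cohort, or `NULL`
#'   when `csv_path` is given.
#' @param missingness a [missingness_config()] or `NULL` for none.
#' @param csv_path path to a cohort CSV instead of a synthetic cohort.
#' @param model_config path to the model-coefficient YAML (default: the
#'   synthetic transcription shipped with the package).
#' @param m number of imputations.
#' @param thresholds decision-curve threshold grid.
#' @param scenario_targets `"from_reference"` (use the reference method's
#'   observed flagged fraction and sensitivity on the same data) or
#'   `list(fraction =, sensitivity =)`.
#' @param seed integer seed driving generation, missingness and imputation.
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(generator = generator_config(),
                            missingness = missingness_config(),
                            csv_path = NULL,
                            model_config = system.file("extdata",
                              "model_config_synthetic.yaml", package = "gdmscreen"),
                            m = 10L,
                            thresholds = seq(0.005, 0.30, by = 0.005),
                            scenario_targets = "from_reference",
                            seed = 1L) {
  if (!is.null(csv_path) && !is.null(generator)) {
    stop("give exactly one input source: generator or csv_path")
  }
  if (is.null(csv_path) && is.null(generator)) {
    stop("one input source required: generator or csv_path")
  }
  structure(list(generator = generator, missingness = missingness,
                 csv_path = csv_path, model_config = model_config, m = as.integer(m),
                 thresholds = thresholds, scenario_targets = scenario_targets,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

#' Run the full screening comparison
#'
#' Executes the staged analysis: obtain the cohort, inject configured
#' missingness, impute `m` data sets, evaluate the single-risk-factor
#' reference method, recalibrate each published model per imputation and pool
#' the updating coefficients by Rubin's rules, extend each with ln(glucose),
#' test the extension by likelihood-ratio chi-square per imputation, pool
#' c-statistics (Hanley-McNeil variances), compute decision curves for the
#' updated (glucose-extended) models against the reference, run the
#' fixed-fraction (A) and fixed-sensitivity (B) scenarios, and build the
#' reclassification table of the best scenario model against the reference.
#' Deterministic given the configuration seed.
#'
#' @param config an [analysis_config()].
#' @return list of class `analysis_report`; see README for the layout.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  mc <- load_model_config(config$model_config)
  ref_cfg <- mc$reference_method

  if (!is.null(config$csv_path)) {
    cohort <- read_cohort_csv(config$csv_path)
  } else {
    gen <- config$generator
    gen$seed <- config$seed
    cohort <- generate_cohort(gen)
    if (!is.null(config$missingness)) {
      msc <- config$missingness
      msc$seed <- config$seed + 1L
      cohort <- apply_missingness(cohort, msc)
    }
  }
  n <- nrow(cohort)

  imp <- if (anyNA(cohort)) {
    impute(cohort, m = config$m, seed = config$seed + 2L)
  } else {
    structure(list(m = config$m, tables = rep(list(cohort), config$m),
                   seed = config$seed + 2L, iterations = 0L),
              class = "imputed_set")
  }
  tables <- imp$tables
  m <- imp$m

  ref_flags_by_imp <- lapply(tables, function(tbl) {
    reference_classify(tbl, bmi_cutoff = ref_cfg$bmi_cutoff,
                       high_prevalence_ethnicities = ref_cfg$high_prevalence_ethnicities,
                       bmi_strict = ref_cfg$bmi_strict)
  })
  reference <- .pool_strategy_performance(ref_flags_by_imp, tables,
                                          flags = TRUE)

  models_out <- lapply(mc$models, function(model) {
    .evaluate_model(model, tables, m)
  })

  # decision curves: reference + the four updated (glucose-extended) models
  strategies <- lapply(names(mc$models), function(nm) {
    model <- mc$models[[nm]]
    coefs <- models_out[[nm]]
    function(tbl) .extended_risk(model, tbl,
      coefs$recalibration$intercept$qbar, coefs$recalibration$slope$qbar,
      coefs$extension$intercept$qbar, coefs$extension$lp_coefficient$qbar,
      coefs$extension$glucose_coefficient$qbar)
  })
  names(strategies) <- names(mc$models)
  ref_strategy <- function(tbl) {
    reference_classify(tbl, bmi_cutoff = ref_cfg$bmi_cutoff,
                       high_prevalence_ethnicities = ref_cfg$high_prevalence_ethnicities,
                       bmi_strict = ref_cfg$bmi_strict)
  }
  curves <- decision_curve(imp, c(list(reference = ref_strategy), strategies),
                           grid = config$thresholds)

  # scenario targets
  if (identical(config$scenario_targets, "from_reference")) {
    targets <- list(fraction = reference$flagged_fraction,
                    sensitivity = reference$sensitivity$qbar)
  } else {
    targets <- config$scenario_targets
  }

  scenarios <- lapply(names(mc$models), function(nm) {
    risks_by_imp <- lapply(tables, strategies[[nm]])
    a <- .pool_scenarios(risks_by_imp, tables, scenario_fixed_fraction,
                         targets$fraction)
    b <- .pool_scenarios(risks_by_imp, tables, scenario_fixed_sensitivity,
                         targets$sensitivity)
    list(A = a, B = b)
  })
  names(scenarios) <- names(mc$models)

  # reclassification: best model in scenario A (highest mean sensitivity)
  sens_a <- vapply(scenarios, function(s) s$A$sensitivity, numeric(1))
  best <- names(which.max(sens_a))
  reclass <- .pool_reclassification(ref_flags_by_imp,
                                    lapply(tables, strategies[[best]]),
                                    tables, targets$fraction)

  structure(list(
    provenance = list(seed = config$seed, m = m, n = n,
                      model_config = basename(config$model_config),
                      package_version = as.character(utils::packageVersion("gdmscreen"))),
    scenario_targets = targets,
    reference = reference,
    models = models_out,
    decision_curves = curves,
    scenarios = scenarios,
    best_model = best,
    reclassification = reclass
  ), class = "analysis_report")
}

# per-imputation recalibration + extension + LR, Rubin-pooled coefficients
# and c-statistics
.evaluate_model <- function(model, tables, m) {
  recals <- lapply(tables, function(tbl) recalibrate(model, tbl))
  exts <- Map(function(recal, tbl) extend_with_glucose(recal, model, tbl),
              recals, tables)
  lrs <- Map(function(recal, ext) lr_test(recal$log_likelihood,
                                          ext$log_likelihood, df = 1L),
             recals, exts)
  pool_par <- function(objs, get_est, get_var) {
    rubin_pool(vapply(objs, get_est, numeric(1)),
               vapply(objs, get_var, numeric(1)))
  }
  recal_pooled <- list(
    intercept = pool_par(recals, function(r) r$calibration_intercept,
                         function(r) r$vcov[1L, 1L]),
    slope = pool_par(recals, function(r) r$calibration_slope,
                     function(r) r$vcov[2L, 2L])
  )
  ext_pooled <- list(
    intercept = pool_par(exts, function(e) e$intercept, function(e) e$vcov[1L, 1L]),
    lp_coefficient = pool_par(exts, function(e) e$lp_coefficient,
                              function(e) e$vcov[2L, 2L]),
    glucose_coefficient = pool_par(exts, function(e) e$glucose_coefficient,
                                   function(e) e$vcov[3L, 3L])
  )

  # score each imputation with the POOLED coefficients, then pool c
  c_of <- function(risk_fun) {
    ests <- vars <- numeric(length(tables))
    for (i in seq_along(tables)) {
      tbl <- tables[[i]]
      risks <- risk_fun(tbl)
      auc <- c_statistic(risks, tbl$gdm)
      ests[i] <- auc
      vars[i] <- c_statistic_variance(auc, sum(tbl$gdm == 1), sum(tbl$gdm == 0))
    }
    rubin_pool(ests, vars)
  }
  c_recal <- c_of(function(tbl) .recalibrated_risk(model, tbl,
    recal_pooled$intercept$qbar, recal_pooled$slope$qbar))
  c_ext <- c_of(function(tbl) .extended_risk(model, tbl,
    recal_pooled$intercept$qbar, recal_pooled$slope$qbar,
    ext_pooled$intercept$qbar, ext_pooled$lp_coefficient$qbar,
    ext_pooled$glucose_coefficient$qbar))

  chis <- vapply(lrs, `[[`, numeric(1), "chi_square")
  ps <- vapply(lrs, `[[`, numeric(1), "p_value")
  list(
    recalibration = recal_pooled,
    extension = ext_pooled,
    c_statistic = c_recal,
    c_statistic_glucose = c_ext,
    lr_test = list(median_chi_square = stats::median(chis),
                   median_p = stats::median(ps),
                   fraction_significant = mean(ps < 0.05),
                   per_imputation_chi_square = chis,
                   per_imputation_p = ps)
  )
}

.pool_strategy_performance <- function(flags_by_imp, tables, flags = TRUE) {
  m <- length(tables)
  per <- lapply(seq_len(m), function(i) {
    classification_measures(flags_by_imp[[i]], tables[[i]]$gdm)
  })
  pool_measure <- function(name) {
    ests <- vapply(per, function(p) p[[name]]$estimate, numeric(1))
    denom <- vapply(per, function(p) {
      cts <- p$counts
      switch(name,
             sensitivity = cts["TP"] + cts["FN"],
             specificity = cts["TN"] + cts["FP"],
             ppv = cts["TP"] + cts["FP"],
             npv = cts["TN"] + cts["FN"])
    }, numeric(1))
    vars <- ests * (1 - ests) / denom
    rubin_pool(ests, vars)
  }
  cs <- vapply(seq_len(m), function(i) {
    c_statistic(as.numeric(flags_by_imp[[i]]), tables[[i]]$gdm)
  }, numeric(1))
  cvars <- vapply(seq_len(m), function(i) {
    c_statistic_variance(cs[i], sum(tables[[i]]$gdm == 1),
                         sum(tables[[i]]$gdm == 0))
  }, numeric(1))
  list(
    flagged_fraction = mean(vapply(flags_by_imp, mean, numeric(1))),
    sensitivity = pool_measure("sensitivity"),
    specificity = pool_measure("specificity"),
    ppv = pool_measure("ppv"),
    npv = pool_measure("npv"),
    c_statistic = rubin_pool(cs, cvars),
    counts = Reduce(`+`, lapply(per, `[[`, "counts")) / m
  )
}

.pool_scenarios <- function(risks_by_imp, tables, scenario_fun, target) {
  per <- Map(function(risks, tbl) scenario_fun(risks, tbl$gdm, target),
             risks_by_imp, tables)
  list(
    target = target,
    threshold = mean(vapply(per, `[[`, numeric(1), "threshold")),
    flagged_fraction = mean(vapply(per, `[[`, numeric(1), "flagged_fraction")),
    sensitivity = mean(vapply(per, `[[`, numeric(1), "sensitivity")),
    specificity = mean(vapply(per, `[[`, numeric(1), "specificity"))
  )
}

.pool_reclassification <- function(ref_flags_by_imp, risks_by_imp, tables,
                                   target_fraction) {
  per <- Map(function(ref, risks, tbl) {
    model_flags <- scenario_fixed_fraction(risks, tbl$gdm, target_fraction)$flags
    reclassification_table(ref, model_flags, tbl$gdm)
  }, ref_flags_by_imp, risks_by_imp, tables)
  counts <- Reduce(`+`, lapply(per, `[[`, "counts")) / length(per)
  list(counts = counts,
       delta_cases_flagged = mean(vapply(per, `[[`, numeric(1), "delta_cases_flagged")),
       delta_noncases_flagged = mean(vapply(per, `[[`, numeric(1), "delta_noncases_flagged")))
}
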