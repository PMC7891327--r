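# Cohort CSV reading/writing and report serialisation.

#' Read a cohort CSV
#'
#' Expects one header row with the cohort schema column names (booleans as
#' 0/1, ethnicity/education/conception as their category labels, empty cells
#' as missing). `sbp_mmhg` may be absent when no loaded model needs it; all
#' other columns are required. Rows whose BMI disagrees with
#' weight/height^2 by more than 0.1 raise a validation warning listing the
#' rows.
#'
#' @param path CSV file path.
#' @return validated cohort `data.frame`.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("cohort CSV not found: ", path)
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
  required <- setdiff(.cohort_columns, "sbp_mmhg")
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols)) {
    stop("cohort CSV lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  unknown <- setdiff(names(tbl), .cohort_columns)
  if (length(unknown)) {
    stop("unknown column(s) in cohort CSV: ", paste(unknown, collapse = ", "))
  }
  num_cols <- c("age_years", "height_cm", "weight_kg", "bmi", "sbp_mmhg",
                "glucose_mmol_l")
  for (col in intersect(num_cols, names(tbl))) {
    if (!is.numeric(tbl[[col]])) {
      bad <- which(!is.na(tbl[[col]]) & is.na(suppressWarnings(as.numeric(tbl[[col]]))))
      stop("unparseable numeric value(s) in column '", col, "', row(s) ",
           paste(utils::head(bad, 5L), collapse = ", "))
    }
  }
  for (col in c("ethnicity", "education", "conception")) {
    lv <- switch(col, ethnicity = .ethnicity_levels,
                 education = .education_levels, conception = .conception_levels)
    bad <- which(!is.na(tbl[[col]]) & !tbl[[col]] %in% lv)
    if (length(bad)) {
      stop("invalid ", col, " value(s) in row(s) ",
           paste(utils::head(bad, 5L), collapse = ", "))
    }
  }
  ok <- stats::complete.cases(tbl[, c("bmi", "weight_kg", "height_cm")])
  dev <- abs(tbl$bmi - tbl$weight_kg / (tbl$height_cm / 100)^2)
  bad <- which(ok & dev > 0.1)
  if (length(bad)) {
    warning("BMI inconsistent with weight/height^2 in row(s) ",
            paste(utils::head(bad, 10L), collapse = ", "))
  }
  if (anyNA(tbl$gdm)) stop("outcome column 'gdm' contains missing values")
  tbl
}

#' Write a cohort CSV
#'
#' @param cohort cohort `data.frame`.
#' @param path destination path.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

.pooled_to_list <- function(p) {
  list(estimate = p$qbar, ci_low = p$ci_low, ci_high = p$ci_high,
       W = p$W, B = p$B, T = p$T, m = p$m)
}

#' Serialise an analysis report to disk
#'
#' Writes `report.json` (the full machine-readable report),
#' `decision_curves.csv` (threshold, strategy, net_benefit) and
#' `manifest.json` into `dir`.
#'
#' @param report an `analysis_report` from [run_analysis()].
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  json <- list(
    provenance = report$provenance,
    scenario_targets = report$scenario_targets,
    reference = list(
      flagged_fraction = report$reference$flagged_fraction,
      sensitivity = .pooled_to_list(report$reference$sensitivity),
      specificity = .pooled_to_list(report$reference$specificity),
      ppv = .pooled_to_list(report$reference$ppv),
      npv = .pooled_to_list(report$reference$npv),
      c_statistic = .pooled_to_list(report$reference$c_statistic),
      counts = as.list(report$reference$counts)
    ),
    models = lapply(report$models, function(mo) list(
      recalibration = lapply(mo$recalibration, .pooled_to_list),
      extension = lapply(mo$extension, .pooled_to_list),
      c_statistic = .pooled_to_list(mo$c_statistic),
      c_statistic_glucose = .pooled_to_list(mo$c_statistic_glucose),
      lr_test = mo$lr_test[c("median_chi_square", "median_p",
                             "fraction_significant")]
    )),
    scenarios = report$scenarios,
    best_model = report$best_model,
    reclassification = list(
      counts = as.list(report$reclassification$counts),
      delta_cases_flagged = report$reclassification$delta_cases_flagged,
      delta_noncases_flagged = report$reclassification$delta_noncases_flagged
    )
  )
  report_path <- file.path(dir, "report.json")
  jsonlite::write_json(json, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  dc_path <- file.path(dir, "decision_curves.csv")
  utils::write.csv(report$decision_curves, dc_path, row.names = FALSE)
  manifest <- list(files = c("report.json", "decision_curves.csv"),
                   seed = report$provenance$seed)
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE)
  invisible(c(report_path, dc_path, manifest_path))
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>  n =", x$provenance$n, " m =", x$provenance$m,
      " seed =", x$provenance$seed, "\n")
  cat(sprintf("reference method: flags %.1f%%, sens %.2f, spec %.2f, c %.2f\n",
              100 * x$reference$flagged_fraction,
              x$reference$sensitivity$qbar, x$reference$specificity$qbar,
              x$reference$c_statistic$qbar))
  for (nm in names(x$models)) {
    mo <- x$models[[nm]]
    cat(sprintf("%-20s c %.3f -> %.3f with glucose (median LR chi2 %.2f)\n",
                nm, mo$c_statistic$qbar, mo$c_statistic_glucose$qbar,
                mo$lr_test$median_chi_square))
  }
  cat("best scenario model:", x$best_model, "\n")
  invisible(x)
}
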