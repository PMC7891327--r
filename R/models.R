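# Cohort schema shared by the generator, the scorers and the CSV reader.
.cohort_columns <- c(
  "age_years", "height_cm", "weight_kg", "bmi", "sbp_mmhg", "glucose_mmol_l",
  "ethnicity", "education", "smoking", "family_history_dm", "conception",
  "parity", "history_gdm", "history_macrosomia", "gdm"
)
.ethnicity_levels  <- c("caucasian", "african", "asian", "mixed", "other")
.education_levels  <- c("low", "medium", "high")
.conception_levels <- c("spontaneous", "ovulation_drugs", "ivf")

# Predictor sets of the four published first-trimester models, as stated in
# the source literature: ethnicity, BMI and history of GDM in all four; age in
# all but van Leeuwen 2010; family history of diabetes in Teede 2011 and
# van Leeuwen 2010; parity in Nanda 2011 and van Leeuwen 2010; history of
# macrosomia only in Nanda 2011; systolic blood pressure only in
# Gabbay-Benziv 2014.
.published_predictor_sets <- list(
  gabbay_benziv_2014 = c("ethnicity", "bmi", "history_gdm", "age_years", "sbp_mmhg"),
  nanda_2011 = c("ethnicity", "bmi", "history_gdm", "age_years", "parity", "history_macrosomia"),
  teede_2011 = c("ethnicity", "bmi", "history_gdm", "age_years", "family_history_dm"),
  van_leeuwen_2010 = c("ethnicity", "bmi", "history_gdm", "family_history_dm", "parity")
)

#' Declarative logistic risk equation
#'
#' A `model_spec` holds one first-trimester GDM risk equation: an intercept
#' plus terms of the form coefficient x transformed predictor. Transformations
#' are `identity`, `natural_log`, or `indicator` (1 when a categorical
#' predictor equals `level`). For the four published model names the predictor
#' set is validated against the published equations; `custom` models accept
#' any schema column.
#'
#' @param name one of `gabbay_benziv_2014`, `nanda_2011`, `teede_2011`,
#'   `van_leeuwen_2010`, `custom`.
#' @param intercept numeric intercept on the logit scale.
#' @param terms list of terms; each term a list with `predictor`,
#'   `transform` (`"identity"`, `"natural_log"`, `"indicator"`),
#'   `coefficient`, and (for indicators) `level`.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(name, intercept, terms = list()) {
  known <- c(names(.published_predictor_sets), "custom")
  if (!is.character(name) || length(name) != 1L || !name %in% known) {
    stop("model name must be one of: ", paste(known, collapse = ", "))
  }
  if (!is.numeric(intercept) || length(intercept) != 1L || !is.finite(intercept)) {
    stop("intercept must be a single finite number")
  }
  terms <- lapply(terms, .validate_term)
  if (name != "custom") {
    got <- sort(unique(vapply(terms, `[[`, character(1), "predictor")))
    want <- sort(.published_predictor_sets[[name]])
    if (!identical(got, want)) {
      stop(sprintf(
        "predictor set for '%s' must be exactly {%s}; got {%s}",
        name, paste(want, collapse = ", "), paste(got, collapse = ", ")
      ))
    }
  }
  structure(list(name = name, intercept = intercept, terms = terms),
            class = "model_spec")
}

.validate_term <- function(term) {
  if (is.null(term$predictor) || !term$predictor %in% setdiff(.cohort_columns, "gdm")) {
    stop("unknown predictor in model term: ", deparse(term$predictor))
  }
  transform <- term$transform %||% "identity"
  if (!transform %in% c("identity", "natural_log", "indicator")) {
    stop("unknown transform '", transform, "' for predictor ", term$predictor)
  }
  if (transform == "indicator" && is.null(term$level)) {
    stop("indicator term on ", term$predictor, " needs a 'level'")
  }
  if (!is.numeric(term$coefficient) || !is.finite(term$coefficient)) {
    stop("coefficient for ", term$predictor, " must be a finite number")
  }
  list(predictor = term$predictor, transform = transform,
       level = term$level %||% NA_character_,
       coefficient = as.numeric(term$coefficient))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Linear predictor of a risk model
#'
#' Evaluates intercept + sum(coefficient x transformed predictor) row-wise.
#' Any missing value in a required predictor is an error: imputation must
#' precede scoring.
#'
#' @param model a [model_spec()].
#' @param data a cohort `data.frame` (one row per pregnancy).
#' @return numeric vector of logits, one per row.
#' @export
linear_predictor <- function(model, data) {
  stopifnot(inherits(model, "model_spec"), is.data.frame(data))
  lp <- rep(model$intercept, nrow(data))
  for (term in model$terms) {
    x <- data[[term$predictor]]
    if (is.null(x)) stop("cohort lacks predictor column '", term$predictor, "'")
    if (anyNA(x)) {
      stop("missing values in required predictor '", term$predictor,
           "' (rows ", paste(utils::head(which(is.na(x)), 5L), collapse = ", "),
           "...); impute before scoring")
    }
    v <- switch(term$transform,
      identity = as.numeric(x),
      natural_log = {
        if (any(x <= 0)) stop("non-positive values in '", term$predictor,
                              "' cannot be log-transformed")
        log(as.numeric(x))
      },
      indicator = as.numeric(x == term$level)
    )
    lp <- lp + term$coefficient * v
  }
  lp
}

#' Risk from a linear predictor
#'
#' Standard logistic link: 1 / (1 + exp(-lp)).
#'
#' @param lp numeric vector of finite logits.
#' @return probabilities in (0, 1).
#' @export
predicted_risk <- function(lp) {
  if (any(!is.finite(lp))) stop("linear predictor must be finite")
  stats::plogis(lp)
}

#' Single-risk-factor reference classification
#'
#' The rule-based reference method flags a woman as high-risk for GDM when at
#' least one risk factor is present: BMI above the cut-off, previous
#' macrosomia, history of GDM, first-degree family history of diabetes, or an
#' ethnicity in the configured non-western high-prevalence set. The BMI rule
#' is strict (`bmi > bmi_cutoff`) by default.
#'
#' @param data cohort `data.frame`.
#' @param bmi_cutoff numeric BMI threshold (kg/m^2), default 30.
#' @param high_prevalence_ethnicities character vector of ethnicity categories
#'   treated as non-western with high diabetes prevalence.
#' @param bmi_strict flag BMI strictly above (`TRUE`, default) or at-or-above
#'   the cut-off.
#' @return logical vector, `TRUE` = high-risk.
#' @export
reference_classify <- function(data, bmi_cutoff = 30,
                               high_prevalence_ethnicities = c("asian", "other"),
                               bmi_strict = TRUE) {
  needed <- c("bmi", "history_macrosomia", "history_gdm", "family_history_dm", "ethnicity")
  for (col in needed) {
    if (is.null(data[[col]])) stop("cohort lacks rule column '", col, "'")
    if (anyNA(data[[col]])) stop("missing values in rule column '", col, "'")
  }
  bmi_rule <- if (bmi_strict) data$bmi > bmi_cutoff else data$bmi >= bmi_cutoff
  bmi_rule |
    as.logical(data$history_macrosomia) |
    as.logical(data$history_gdm) |
    as.logical(data$family_history_dm) |
    data$ethnicity %in% high_prevalence_ethnicities
}

#' Load risk-model configuration from YAML
#'
#' Reads a YAML file with a `models:` list (name, intercept, terms with
#' predictor / transform / level / coefficient) and an optional
#' `reference_method:` block (`bmi_cutoff`, `high_prevalence_ethnicities`).
#' Each named published model's predictor set is validated against its
#' published equation.
#'
#' @param path path to the YAML file.
#' @return list with elements `models` (named list of [model_spec()]) and
#'   `reference_method` (list of rule settings).
#' @export
load_model_config <- function(path) {
  if (!file.exists(path)) stop("model config not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$models)) stop("model config must contain a 'models' list")
  models <- lapply(cfg$models, function(m) {
    if (is.null(m$name)) stop("every model entry needs a 'name'")
    if (is.null(m$intercept)) stop("model '", m$name, "' lacks an intercept")
    model_spec(m$name, m$intercept, m$terms %||% list())
  })
  names(models) <- vapply(models, `[[`, character(1), "name")
  ref <- cfg$reference_method %||% list()
  ref$bmi_cutoff <- ref$bmi_cutoff %||% 30
  ref$high_prevalence_ethnicities <-
    unlist(ref$high_prevalence_ethnicities %||% c("asian", "other"))
  ref$bmi_strict <- ref$bmi_strict %||% TRUE
  bad <- setdiff(ref$high_prevalence_ethnicities, .ethnicity_levels)
  if (length(bad)) stop("unknown ethnicity in reference_method: ",
                        paste(bad, collapse = ", "))
  list(models = models, reference_method = ref)
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec>", x$name, "\n intercept:", x$intercept, "\n")
  for (t in x$terms) {
    lvl <- if (!is.na(t$level)) paste0("[", t$level, "]") else ""
    cat(sprintf("  %+0.4f * %s(%s%s)\n", t$coefficient, t$transform,
                t$predictor, lvl))
  }
  invisible(x)
}
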