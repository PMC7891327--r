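# Decision-curve analysis (net benefit) and fixed-operating-point scenarios.

#' Net benefit of a screening strategy at a threshold probability
#'
#' Net benefit at threshold `pt` is the true-positive fraction minus the
#' false-positive fraction weighted by the odds pt/(1-pt). For a risk model,
#' subjects with risk >= pt are flagged; a fixed binary classifier can be
#' passed as logical `risks` (its flags are used for all pt, the weight
#' still varies).
#'
#' @param risks numeric predicted risks, or a logical flag vector.
#' @param outcomes binary outcomes.
#' @param pt threshold probability in (0, 1).
#' @return net benefit (units: net true positives per subject).
#' @export
net_benefit <- function(risks, outcomes, pt) {
  if (pt <= 0 || pt >= 1) stop("threshold probability pt must lie in (0,1)")
  outcomes <- as.logical(outcomes)
  flags <- if (is.logical(risks)) risks else risks >= pt
  n <- length(outcomes)
  tp <- sum(flags & outcomes)
  fp <- sum(flags & !outcomes)
  tp / n - (fp / n) * pt / (1 - pt)
}

#' Decision curves over a threshold grid, pooled over imputations
#'
#' Each strategy is a function of a completed cohort table returning either
#' numeric risks or logical flags (the rule-based reference method). The
#' treat-all and treat-none strategies are always included. Net benefit is
#' computed per imputation and averaged (Rubin point-estimate pooling).
#'
#' @param imputed an `imputed_set` (or a single complete `data.frame`).
#' @param strategies named list of functions `function(tbl) -> risks|flags`.
#' @param grid threshold probabilities, all in (0, 1); default 0.005-0.30 by
#'   0.005, which covers the informative 2-12% region.
#' @return data.frame of class `decision_curve`: threshold, strategy,
#'   net_benefit.
#' @export
decision_curve <- function(imputed, strategies,
                           grid = seq(0.005, 0.30, by = 0.005)) {
  if (!length(grid)) stop("empty threshold grid")
  if (any(grid <= 0 | grid >= 1)) stop("grid thresholds must lie in (0,1)")
  tables <- if (inherits(imputed, "imputed_set")) imputed$tables else list(imputed)
  if (length(strategies) &&
      (is.null(names(strategies)) || any(names(strategies) == ""))) {
    stop("strategies must be a named list")
  }
  all_strategies <- c(strategies,
                      list(treat_all = function(tbl) rep(TRUE, nrow(tbl)),
                           treat_none = function(tbl) rep(FALSE, nrow(tbl))))
  nb <- vapply(names(all_strategies), function(s) {
    per_imp <- vapply(tables, function(tbl) {
      scored <- all_strategies[[s]](tbl)
      vapply(grid, function(pt) net_benefit(scored, tbl$gdm, pt), numeric(1))
    }, numeric(length(grid)))
    rowMeans(matrix(per_imp, nrow = length(grid)))
  }, numeric(length(grid)))
  nb <- matrix(nb, nrow = length(grid),
               dimnames = list(NULL, names(all_strategies)))
  out <- data.frame(
    threshold = rep(grid, times = ncol(nb)),
    strategy = rep(colnames(nb), each = length(grid)),
    net_benefit = as.numeric(nb),
    stringsAsFactors = FALSE
  )
  class(out) <- c("decision_curve", "data.frame")
  out
}

# flag the k highest risks, stable in original row order among ties
.flag_top_k <- function(risks, k) {
  n <- length(risks)
  flags <- logical(n)
  if (k > 0L) flags[order(-risks)[seq_len(k)]] <- TRUE
  flags
}

.scenario_result <- function(scenario, threshold, flags, outcomes) {
  outcomes <- as.logical(outcomes)
  tp <- sum(flags & outcomes); fp <- sum(flags & !outcomes)
  fn <- sum(!flags & outcomes); tn <- sum(!flags & !outcomes)
  structure(list(
    scenario = scenario, threshold = threshold,
    flagged_fraction = mean(flags),
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    flags = flags
  ), class = "scenario_result")
}

#' Scenario A: hold the flagged fraction constant
#'
#' Chooses the risk cut-off so the model flags (as near as attainable) the
#' same proportion of women as the reference method; ties at the cut-off are
#' broken by descending risk in stable row order and the attained fraction is
#' reported.
#'
#' @param risks predicted risks.
#' @param outcomes binary outcomes.
#' @param target_fraction proportion to classify high-risk, in (0, 1).
#' @return `scenario_result`: threshold, attained `flagged_fraction`,
#'   `sensitivity`, `specificity`, and the flag vector.
#' @export
scenario_fixed_fraction <- function(risks, outcomes, target_fraction) {
  if (target_fraction <= 0 || target_fraction >= 1) {
    stop("target_fraction must lie in (0,1)")
  }
  n <- length(risks)
  if (stats::sd(risks) < 1e-12) {
    stop("constant risks: no cut-off can attain the target fraction")
  }
  k <- floor(target_fraction * n)
  flags <- .flag_top_k(risks, k)
  threshold <- if (k > 0L) min(risks[flags]) else Inf
  .scenario_result("A", threshold, flags, outcomes)
}

#' Scenario B: hold sensitivity constant
#'
#' Chooses the largest cut-off whose sensitivity reaches the target (the
#' smallest high-risk group that still detects the target share of cases);
#' reports the attained flagged fraction and specificity.
#'
#' @param risks predicted risks.
#' @param outcomes binary outcomes; cases must be present.
#' @param target_sens sensitivity to attain, in (0, 1].
#' @return `scenario_result` as for [scenario_fixed_fraction()].
#' @export
scenario_fixed_sensitivity <- function(risks, outcomes, target_sens) {
  if (target_sens <= 0 || target_sens > 1) stop("target_sens must lie in (0,1]")
  outcomes <- as.logical(outcomes)
  n_cases <- sum(outcomes)
  if (n_cases == 0L) stop("no cases: sensitivity undefined")
  case_risks <- sort(risks[outcomes], decreasing = TRUE)
  need <- ceiling(target_sens * n_cases)
  threshold <- case_risks[need]
  flags <- risks >= threshold
  res <- .scenario_result("B", threshold, flags, outcomes)
  if (res$sensitivity < target_sens) {
    stop("no threshold attains the target sensitivity (ties at the minimum case risk)")
  }
  res
}

#' Reclassification table: model versus reference classification by outcome
#'
#' Full 2 x 2 x 2 cross-tabulation of (outcome, reference class, model
#' class), plus the headline deltas: additional cases flagged by the model
#' and the reduction in flagged non-cases, relative to the reference.
#'
#' @param ref_flags logical reference-method flags.
#' @param model_flags logical model flags.
#' @param outcomes binary outcomes.
#' @return list of class `reclassification_table`: `counts` (named 8-vector),
#'   `delta_cases_flagged`, `delta_noncases_flagged`.
#' @export
reclassification_table <- function(ref_flags, model_flags, outcomes) {
  ref_flags <- as.logical(ref_flags)
  model_flags <- as.logical(model_flags)
  outcomes <- as.logical(outcomes)
  if (length(unique(c(length(ref_flags), length(model_flags), length(outcomes)))) != 1L) {
    stop("input lengths differ")
  }
  cell <- function(o, r, m) sum(outcomes == o & ref_flags == r & model_flags == m)
  counts <- c(
    gdm_ref_high_model_high = cell(TRUE, TRUE, TRUE),
    gdm_ref_high_model_low = cell(TRUE, TRUE, FALSE),
    gdm_ref_low_model_high = cell(TRUE, FALSE, TRUE),
    gdm_ref_low_model_low = cell(TRUE, FALSE, FALSE),
    nogdm_ref_high_model_high = cell(FALSE, TRUE, TRUE),
    nogdm_ref_high_model_low = cell(FALSE, TRUE, FALSE),
    nogdm_ref_low_model_high = cell(FALSE, FALSE, TRUE),
    nogdm_ref_low_model_low = cell(FALSE, FALSE, FALSE)
  )
  structure(list(
    counts = counts,
    delta_cases_flagged = sum(model_flags & outcomes) - sum(ref_flags & outcomes),
    delta_noncases_flagged = sum(model_flags & !outcomes) - sum(ref_flags & !outcomes)
  ), class = "reclassification_table")
}
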