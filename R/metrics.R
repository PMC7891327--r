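# Discrimination, classification accuracy and calibration.

#' Concordance statistic (c-statistic / AUC)
#'
#' Probability that a randomly chosen case receives a higher predicted risk
#' than a randomly chosen non-case, ties counted one half. Computed by the
#' midrank (Wilcoxon) identity in O(n log n); exactly equal to the all-pairs
#' definition.
#'
#' @param risks numeric vector of scores or probabilities.
#' @param outcomes binary outcomes (0/1 or logical).
#' @return c-statistic in `[0, 1]`.
#' @export
c_statistic <- function(risks, outcomes) {
  outcomes <- as.logical(outcomes)
  if (length(risks) != length(outcomes)) stop("risks and outcomes differ in length")
  if (anyNA(risks) || anyNA(outcomes)) stop("missing values in risks or outcomes")
  n1 <- sum(outcomes)
  n0 <- sum(!outcomes)
  if (n1 == 0L || n0 == 0L) {
    stop("c-statistic undefined: outcomes contain a single class")
  }
  r <- rank(risks, ties.method = "average")
  (sum(r[outcomes]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Hanley-McNeil variance of a c-statistic
#'
#' Closed-form variance approximation used to carry per-imputation
#' c-statistics into Rubin pooling.
#'
#' @param auc the c-statistic.
#' @param n_cases,n_controls class sizes.
#' @return approximate variance of the c-statistic.
#' @export
c_statistic_variance <- function(auc, n_cases, n_controls) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  (auc * (1 - auc) + (n_cases - 1) * (q1 - auc^2) +
     (n_controls - 1) * (q2 - auc^2)) / (n_cases * n_controls)
}

#' Wilson score interval for a binomial proportion
#'
#' @param x number of successes.
#' @param n number of trials.
#' @param conf confidence level.
#' @return c(lower, upper); never degenerate at 0 or 1.
#' @export
wilson_ci <- function(x, n, conf = 0.95) {
  if (n == 0L) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(max(0, centre - half), min(1, centre + half))
}

#' Classification accuracy of a binary screen
#'
#' Cross-tabulates flags against outcomes and derives sensitivity,
#' specificity, PPV and NPV with Wilson score intervals. A measure whose
#' denominator is empty is reported as `NA` with an explanatory `reason`.
#'
#' @param flags logical (or 0/1) vector: `TRUE` = classified high-risk.
#' @param outcomes binary outcomes.
#' @param conf confidence level for the Wilson intervals.
#' @return list of class `classification_measures` with `counts` (TP, FP,
#'   FN, TN) and one `list(estimate, ci_low, ci_high)` per measure.
#' @export
classification_measures <- function(flags, outcomes, conf = 0.95) {
  flags <- as.logical(flags)
  outcomes <- as.logical(outcomes)
  if (length(flags) != length(outcomes)) stop("flags and outcomes differ in length")
  if (!length(flags)) stop("empty input")
  tp <- sum(flags & outcomes)
  fp <- sum(flags & !outcomes)
  fn <- sum(!flags & outcomes)
  tn <- sum(!flags & !outcomes)
  measure <- function(x, n, reason) {
    if (n == 0L) {
      return(list(estimate = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                  reason = reason))
    }
    ci <- wilson_ci(x, n, conf)
    list(estimate = x / n, ci_low = ci[1L], ci_high = ci[2L])
  }
  structure(list(
    counts = c(TP = tp, FP = fp, FN = fn, TN = tn),
    n = length(flags),
    sensitivity = measure(tp, tp + fn, "no cases"),
    specificity = measure(tn, tn + fp, "no non-cases"),
    ppv = measure(tp, tp + fp, "nobody flagged"),
    npv = measure(tn, tn + fn, "everybody flagged")
  ), class = "classification_measures")
}

#' Grouped calibration curve
#'
#' Splits subjects into equal-frequency bins of predicted risk (stable rank
#' order, so tied risks may straddle bins) and reports each bin's mean
#' predicted risk, observed outcome proportion and count, plus a fixed-span
#' moving-average smooth for plotting.
#'
#' @param risks predicted probabilities.
#' @param outcomes binary outcomes.
#' @param n_bins number of equal-frequency bins (>= 2).
#' @param span_frac fraction of subjects in the moving-average window.
#' @return list with `points` (data.frame: bin, mean_pred, obs_prop, count)
#'   and `smooth` (data.frame: pred, obs_smooth).
#' @export
calibration_curve <- function(risks, outcomes, n_bins = 10L, span_frac = 0.1) {
  outcomes <- as.numeric(as.logical(outcomes))
  n <- length(risks)
  if (n_bins < 2L) stop("n_bins must be >= 2")
  if (n_bins > n) stop("n_bins exceeds the number of subjects")
  ord <- order(risks)  # stable
  bin <- ceiling(seq_len(n) / (n / n_bins))
  bin <- pmin(bin, n_bins)
  pts <- data.frame(
    bin = seq_len(n_bins),
    mean_pred = as.numeric(tapply(risks[ord], bin, mean)),
    obs_prop = as.numeric(tapply(outcomes[ord], bin, mean)),
    count = as.integer(tapply(outcomes[ord], bin, length))
  )
  span <- max(25L, ceiling(span_frac * n))
  half <- span %/% 2L
  sm_pred <- sm_obs <- numeric(n)
  r_sorted <- risks[ord]
  y_sorted <- outcomes[ord]
  cs_r <- cumsum(r_sorted)
  cs_y <- cumsum(y_sorted)
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  w <- hi - lo + 1L
  sm_pred <- (cs_r[hi] - c(0, cs_r)[lo]) / w
  sm_obs <- (cs_y[hi] - c(0, cs_y)[lo]) / w
  list(points = pts,
       smooth = data.frame(pred = sm_pred, obs_smooth = sm_obs))
}
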