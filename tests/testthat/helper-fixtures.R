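# Shared fixtures: small cohorts and models built in code.

# a tiny complete cohort with hand-set values, n rows recycled from a base of 8
tiny_cohort <- function(n = 8L) {
  base <- data.frame(
    age_years = c(28, 34, 30, 41, 25, 36, 29, 33),
    height_cm = c(165, 170, 158, 172, 168, 160, 175, 163),
    weight_kg = NA_real_,
    bmi = c(23, 31, 27, 22, 35, 24, 21, 29),
    sbp_mmhg = c(110, 125, 118, 105, 130, 112, 108, 121),
    glucose_mmol_l = c(4.5, 5.2, 4.8, 4.3, 5.6, 4.7, 4.4, 5.0),
    ethnicity = c("caucasian", "asian", "caucasian", "other", "caucasian",
                  "mixed", "caucasian", "african"),
    education = c("high", "medium", "low", "high", "medium", "high", "low",
                  "medium"),
    smoking = c(0L, 1L, 0L, 0L, 1L, 0L, 0L, 0L),
    family_history_dm = c(0L, 1L, 0L, 0L, 1L, 0L, 0L, 1L),
    conception = c("spontaneous", "spontaneous", "ivf", "spontaneous",
                   "ovulation_drugs", "spontaneous", "spontaneous", "ivf"),
    parity = c(0L, 2L, 1L, 0L, 3L, 1L, 0L, 2L),
    history_gdm = c(0L, 1L, 0L, 0L, 0L, 0L, 0L, 0L),
    history_macrosomia = c(0L, 0L, 1L, 0L, 0L, 0L, 0L, 0L),
    gdm = c(0L, 1L, 0L, 0L, 1L, 0L, 0L, 1L),
    stringsAsFactors = FALSE
  )
  base$weight_kg <- base$bmi * (base$height_cm / 100)^2
  out <- base[rep(seq_len(8L), length.out = n), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# intercept + single-predictor model helpers
intercept_only_model <- function(intercept) model_spec("custom", intercept)

lng_model <- function(coef = 1, intercept = 0) {
  model_spec("custom", intercept, list(
    list(predictor = "glucose_mmol_l", transform = "natural_log",
         coefficient = coef)
  ))
}

shipped_config_path <- function() {
  system.file("extdata", "model_config_synthetic.yaml", package = "gdmscreen")
}

# independent all-pairs concordance oracle (O(n^2)), ties one half
c_statistic_allpairs <- function(risks, outcomes) {
  outcomes <- as.logical(outcomes)
  cases <- risks[outcomes]
  controls <- risks[!outcomes]
  tot <- 0
  for (a in cases) tot <- tot + sum(a > controls) + 0.5 * sum(a == controls)
  tot / (length(cases) * length(controls))
}

# brute-force scenario threshold scans over all candidate cut-offs
scenario_a_bruteforce <- function(risks, outcomes, target_fraction) {
  n <- length(risks)
  k <- floor(target_fraction * n)
  cand <- sort(unique(risks), decreasing = TRUE)
  best <- Inf
  for (thr in cand) if (sum(risks >= thr) <= k) best <- thr
  best
}

scenario_b_bruteforce <- function(risks, outcomes, target_sens) {
  outcomes <- as.logical(outcomes)
  n_cases <- sum(outcomes)
  cand <- sort(unique(risks), decreasing = TRUE)
  for (thr in cand) {
    flags <- risks >= thr
    if (sum(flags & outcomes) / n_cases >= target_sens) return(thr)
  }
  NA_real_
}
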