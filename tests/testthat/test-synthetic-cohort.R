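test_that("default generator lands on the target prevalence and is reproducible", {
  cfg <- generator_config(n_subjects = 50000, seed = 42)
  cohort <- generate_cohort(cfg)
  expect_equal(nrow(cohort), 50000)

  prev <- mean(cohort$gdm)
  se <- sqrt(0.049 * 0.951 / 50000)
  expect_lt(abs(prev - 0.049), 3 * se)

  # identical config + seed reproduces the table bit-for-bit
  expect_identical(cohort, generate_cohort(cfg))
  # a different seed gives a different realisation
  expect_false(identical(cohort, generate_cohort(generator_config(n_subjects = 50000, seed = 43))))
})

test_that("an intercept-only outcome mechanism yields its logit-implied prevalence", {
  cfg <- generator_config(
    n_subjects = 50000,
    outcome_model = intercept_only_model(qlogis(0.05)),
    target_prevalence = NULL, seed = 7
  )
  cohort <- generate_cohort(cfg)
  se <- sqrt(0.05 * 0.95 / 50000)
  expect_lt(abs(mean(cohort$gdm) - 0.05), 3 * se)
})

test_that("generated covariate marginals match their configured values", {
  p <- default_covariate_params()
  cohort <- generate_cohort(generator_config(n_subjects = 50000, seed = 3))
  n <- nrow(cohort)

  expect_lt(abs(mean(cohort$age_years) - p$age$mean), 3 * p$age$sd / sqrt(n))
  expect_lt(abs(mean(cohort$sbp_mmhg) - p$sbp$mean), 3 * p$sbp$sd / sqrt(n))
  # medians of the skewed marginals (median SE ~ 1.2533 sd/sqrt(n))
  expect_lt(abs(median(cohort$bmi) - p$bmi$median), 3 * 1.26 * sd(cohort$bmi) / sqrt(n))
  expect_lt(abs(median(cohort$glucose_mmol_l) - p$glucose$median),
            3 * 1.26 * sd(cohort$glucose_mmol_l) / sqrt(n))
  # right-skew of the log-normal marginals
  expect_gt(mean(cohort$bmi), median(cohort$bmi))
  expect_gt(mean(cohort$glucose_mmol_l), median(cohort$glucose_mmol_l))

  for (lv in names(p$ethnicity)) {
    pr <- p$ethnicity[[lv]]
    expect_lt(abs(mean(cohort$ethnicity == lv) - pr),
              3 * sqrt(pr * (1 - pr) / n) + 1e-12)
  }
  expect_lt(abs(mean(cohort$parity == 0) - p$parity[["0"]]),
            3 * sqrt(0.445 * 0.555 / n))
  for (nm in c("smoking", "family_history_dm", "history_gdm", "history_macrosomia")) {
    pr <- p[[nm]]
    expect_lt(abs(mean(cohort[[nm]]) - pr), 4 * sqrt(pr * (1 - pr) / n))
  }
})

test_that("structural invariants hold: BMI identity, history only when parous", {
  cohort <- generate_cohort(generator_config(n_subjects = 20000, seed = 5))
  expect_lt(max(abs(cohort$bmi - cohort$weight_kg / (cohort$height_cm / 100)^2)), 1e-9)
  nullip <- cohort$parity == 0
  expect_true(all(cohort$history_gdm[nullip] == 0))
  expect_true(all(cohort$history_macrosomia[nullip] == 0))
  expect_true(all(cohort$glucose_mmol_l > 0))
})

test_that("empirical prevalence tracks the mean of the true risks", {
  cohort <- generate_cohort(generator_config(n_subjects = 100000, seed = 9))
  true_p <- attr(cohort, "true_lp")
  expected <- mean(plogis(true_p))
  se <- sqrt(sum(plogis(true_p) * (1 - plogis(true_p)))) / length(true_p)
  expect_lt(abs(mean(cohort$gdm) - expected), 3 * se)
})

test_that("invalid generator configurations are rejected with the offending field", {
  p <- default_covariate_params()
  p$age$sd <- -1
  expect_error(generator_config(covariate_params = p), "age")
  p <- default_covariate_params()
  p$ethnicity <- c(caucasian = 0.8, african = 0.1, asian = 0.2, mixed = 0, other = 0)
  expect_error(generator_config(covariate_params = p), "ethnicity")
  p <- default_covariate_params()
  p$smoking <- 1.2
  expect_error(generator_config(covariate_params = p), "smoking")
  expect_error(generator_config(n_subjects = 0), "n_subjects")
  expect_error(generator_config(target_prevalence = 1.5), "target_prevalence")
})

test_that("zero missing rates leave the cohort untouched", {
  cohort <- generate_cohort(generator_config(n_subjects = 500, seed = 1))
  cfg <- missingness_config(rates = list(glucose_mmol_l = 0), seed = 2)
  expect_identical(apply_missingness(cohort, cfg), cohort)
})

test_that("MCAR deletion hits the configured rate and spares the outcome", {
  cohort <- generate_cohort(generator_config(n_subjects = 10000, seed = 21))
  cfg <- missingness_config(rates = list(glucose_mmol_l = 0.2), seed = 22)
  out <- apply_missingness(cohort, cfg)
  frac <- mean(is.na(out$glucose_mmol_l))
  expect_lt(abs(frac - 0.2), 3 * sqrt(0.2 * 0.8 / 10000))
  expect_identical(out$gdm, cohort$gdm)
  expect_false(anyNA(out$gdm))
})

test_that("MAR logistic dependence is recoverable from the missingness indicator", {
  cohort <- generate_cohort(generator_config(n_subjects = 40000, seed = 31))
  cfg <- missingness_config(
    mechanism = "MAR", rates = list(glucose_mmol_l = 0.2),
    mar_dependence = list(covariate = "bmi", weight = 0.15), seed = 32
  )
  out <- apply_missingness(cohort, cfg)
  ind <- as.integer(is.na(out$glucose_mmol_l))
  fit <- glm(ind ~ cohort$bmi, family = binomial())
  est <- coef(fit)[2]
  se <- sqrt(vcov(fit)[2, 2])
  expect_lt(abs(est - 0.15), 3 * se)
  expect_lt(abs(mean(ind) - 0.2), 3 * sqrt(0.2 * 0.8 / 40000))
})

test_that("missingness configuration guards its invariants", {
  expect_error(missingness_config(rates = list(gdm = 0.1)), "gdm")
  expect_error(missingness_config(rates = list(glucose_mmol_l = 1)), "rates")
  expect_error(
    missingness_config(mechanism = "MAR", rates = list(bmi = 0.2),
                       mar_dependence = list(covariate = "bmi", weight = 1)),
    "must not itself"
  )
})
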