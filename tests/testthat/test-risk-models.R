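test_that("the shipped model config loads with the published predictor sets", {
  cfg <- load_model_config(shipped_config_path())
  expect_named(cfg$models, c("gabbay_benziv_2014", "nanda_2011", "teede_2011",
                             "van_leeuwen_2010"))
  preds <- function(m) sort(unique(vapply(m$terms, `[[`, character(1), "predictor")))
  expect_setequal(preds(cfg$models$teede_2011),
                  c("age_years", "bmi", "ethnicity", "family_history_dm", "history_gdm"))
  expect_false("age_years" %in% preds(cfg$models$van_leeuwen_2010))
  expect_true("sbp_mmhg" %in% preds(cfg$models$gabbay_benziv_2014))
  expect_true("history_macrosomia" %in% preds(cfg$models$nanda_2011))
  expect_equal(cfg$reference_method$bmi_cutoff, 30)
})

test_that("predictor-set violations for named published models are rejected", {
  # van Leeuwen 2010 does not use maternal age
  expect_error(
    model_spec("van_leeuwen_2010", -6, list(
      list(predictor = "age_years", transform = "identity", coefficient = 0.1),
      list(predictor = "bmi", transform = "identity", coefficient = 0.1),
      list(predictor = "history_gdm", transform = "identity", coefficient = 1),
      list(predictor = "family_history_dm", transform = "identity", coefficient = 1),
      list(predictor = "parity", transform = "identity", coefficient = 0.1),
      list(predictor = "ethnicity", transform = "indicator", level = "asian",
           coefficient = 1)
    )),
    "predictor set"
  )
  # Teede 2011 with its exact predictor set is accepted
  expect_s3_class(
    model_spec("teede_2011", -8, list(
      list(predictor = "age_years", transform = "identity", coefficient = 0.1),
      list(predictor = "bmi", transform = "identity", coefficient = 0.1),
      list(predictor = "family_history_dm", transform = "identity", coefficient = 1),
      list(predictor = "history_gdm", transform = "identity", coefficient = 1),
      list(predictor = "ethnicity", transform = "indicator", level = "asian",
           coefficient = 1)
    )),
    "model_spec"
  )
  # custom models are free-form, intercept-only included
  expect_s3_class(intercept_only_model(-2.944), "model_spec")
  expect_error(model_spec("custom", -1, list(
    list(predictor = "not_a_column", transform = "identity", coefficient = 1)
  )), "unknown predictor")
})

test_that("linear predictor evaluates intercept + sum of transformed terms", {
  cohort <- tiny_cohort()
  expect_equal(linear_predictor(intercept_only_model(-2.944), cohort),
               rep(-2.944, 8))

  lp <- linear_predictor(lng_model(1), cohort)
  expect_equal(lp, log(cohort$glucose_mmol_l))
  expect_equal(lp[cohort$glucose_mmol_l == 4.7], log(4.7), tolerance = 1e-12)

  # a zero-coefficient term changes nothing
  m0 <- model_spec("custom", 0.5, list(
    list(predictor = "glucose_mmol_l", transform = "natural_log", coefficient = 1),
    list(predictor = "bmi", transform = "identity", coefficient = 0)
  ))
  expect_equal(linear_predictor(m0, cohort), 0.5 + log(cohort$glucose_mmol_l))

  # indicator terms fire only on the matching level
  mi <- model_spec("custom", 0, list(
    list(predictor = "ethnicity", transform = "indicator", level = "asian",
         coefficient = 2)
  ))
  expect_equal(linear_predictor(mi, cohort), 2 * (cohort$ethnicity == "asian"))

  cohort$glucose_mmol_l[3] <- NA
  expect_error(linear_predictor(lng_model(1), cohort), "glucose_mmol_l")
})

test_that("predicted risk is the logistic inverse link, strictly monotone", {
  expect_equal(predicted_risk(0), 0.5)
  expect_equal(predicted_risk(qlogis(0.25)), 0.25, tolerance = 1e-12)
  expect_equal(predicted_risk(-1.0986), 0.25, tolerance = 1e-4)
  lp <- seq(-30, 30, length.out = 201)
  r <- predicted_risk(lp)
  expect_true(all(diff(r) > 0))
  expect_lt(predicted_risk(-30), 1e-10)
  expect_error(predicted_risk(Inf), "finite")
})

test_that("risk is monotone in BMI under a positive BMI coefficient", {
  m <- model_spec("custom", -5, list(
    list(predictor = "bmi", transform = "identity", coefficient = 0.2),
    list(predictor = "age_years", transform = "identity", coefficient = 0.05)
  ))
  cohort <- tiny_cohort(1)[rep(1, 50), ]
  cohort$bmi <- seq(18, 45, length.out = 50)
  risks <- predicted_risk(linear_predictor(m, cohort))
  expect_true(all(diff(risks) > 0))
})

test_that("scoring is row-wise: permuting rows permutes predictions", {
  cfg <- load_model_config(shipped_config_path())
  cohort <- generate_cohort(generator_config(n_subjects = 300, seed = 12))
  perm <- sample(300)
  for (m in cfg$models) {
    lp <- linear_predictor(m, cohort)
    expect_identical(linear_predictor(m, cohort[perm, ]), lp[perm])
  }
})

test_that("reference method fires on any single risk factor", {
  base <- tiny_cohort(1)
  base$bmi <- 23; base$history_macrosomia <- 0L; base$history_gdm <- 0L
  base$family_history_dm <- 0L; base$ethnicity <- "caucasian"
  expect_false(reference_classify(base))

  high_bmi <- base; high_bmi$bmi <- 31
  expect_true(reference_classify(high_bmi))
  fam <- base; fam$family_history_dm <- 1L
  expect_true(reference_classify(fam))

  # BMI rule is strict > 30 by default, >= 30 when configured
  at30 <- base; at30$bmi <- 30
  expect_false(reference_classify(at30))
  expect_true(reference_classify(at30, bmi_strict = FALSE))

  expect_error(reference_classify(transform(base, bmi = NA)), "bmi")
})

test_that("reference method equals the OR of its five single-factor rules", {
  combos <- expand.grid(bmi_high = c(FALSE, TRUE), mac = c(FALSE, TRUE),
                        gdm_hist = c(FALSE, TRUE), fam = c(FALSE, TRUE),
                        eth = c(FALSE, TRUE))
  cohort <- tiny_cohort(nrow(combos))
  cohort$bmi <- ifelse(combos$bmi_high, 32, 24)
  cohort$history_macrosomia <- as.integer(combos$mac)
  cohort$history_gdm <- as.integer(combos$gdm_hist)
  cohort$family_history_dm <- as.integer(combos$fam)
  cohort$ethnicity <- ifelse(combos$eth, "asian", "caucasian")
  cohort$parity <- 2L  # histories require parity > 0
  got <- reference_classify(cohort)
  want <- combos$bmi_high | combos$mac | combos$gdm_hist | combos$fam | combos$eth
  expect_identical(got, want)
})
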