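test_that("net benefit evaluates its defining formula on a printed toy", {
  # n = 10, 2 cases; flags capture TP 2, FP 1 at pt = 0.2
  risks <- c(0.9, 0.8, 0.5, rep(0.05, 7))
  outcomes <- c(1, 1, 0, rep(0, 7))
  expect_equal(net_benefit(risks, outcomes, 0.2), 0.2 - 0.1 * 0.25)

  # treat-all closed form at any prevalence
  prev <- mean(outcomes)
  for (pt in c(0.01, 0.1, 0.3)) {
    expect_equal(net_benefit(rep(TRUE, 10), outcomes, pt),
                 prev - (1 - prev) * pt / (1 - pt), tolerance = 1e-15)
  }
  expect_equal(net_benefit(rep(FALSE, 10), outcomes, 0.1), 0)
  expect_error(net_benefit(risks, outcomes, 0), "pt")
  expect_error(net_benefit(risks, outcomes, 1), "pt")
})

test_that("net benefit is non-increasing in pt for a fixed flag set", {
  set.seed(31)
  outcomes <- rbinom(500, 1, 0.1)
  flags <- as.logical(rbinom(500, 1, 0.3))
  grid <- seq(0.01, 0.5, by = 0.01)
  nb <- vapply(grid, function(pt) net_benefit(flags, outcomes, pt), numeric(1))
  expect_true(all(diff(nb) <= 1e-15))
})

test_that("decision curves pool degenerately over identical imputations", {
  cohort <- generate_cohort(generator_config(n_subjects = 1500, seed = 32))
  imp <- impute(cohort, m = 3, seed = 33)  # complete -> identical copies
  risk_fun <- function(tbl) predicted_risk(attr(cohort, "true_lp"))
  grid <- seq(0.01, 0.2, by = 0.01)
  dc <- decision_curve(imp, list(model = risk_fun), grid = grid)
  single <- decision_curve(cohort, list(model = risk_fun), grid = grid)
  expect_equal(dc$net_benefit, single$net_benefit)

  # treat_none is identically zero; every strategy <= prevalence
  expect_true(all(dc$net_benefit[dc$strategy == "treat_none"] == 0))
  expect_true(all(dc$net_benefit <= mean(cohort$gdm) + 1e-12))
  # near pt = 0 treat_all approaches prevalence
  lo <- decision_curve(cohort, list(), grid = 1e-4)
  expect_lt(abs(lo$net_benefit[lo$strategy == "treat_all"] - mean(cohort$gdm)),
            2e-4)
  expect_error(decision_curve(imp, list(model = risk_fun), grid = numeric(0)),
               "empty")
})

test_that("scenario A flags exactly the target count with distinct risks", {
  risks <- c(0.91, 0.82, 0.75, 0.64, 0.55, 0.42, 0.33, 0.21, 0.12, 0.05)
  outcomes <- c(1, 0, 1, 0, 0, 1, 0, 0, 0, 0)
  res <- scenario_fixed_fraction(risks, outcomes, 0.3)
  expect_equal(sum(res$flags), 3)
  expect_equal(res$flagged_fraction, 0.3)
  expect_equal(res$sensitivity, 2 / 3)  # cases among the top 3 risks
  expect_equal(res$threshold, 0.75)

  near_all <- scenario_fixed_fraction(risks, outcomes, 0.99)
  expect_equal(near_all$sensitivity, 1)
  expect_equal(near_all$specificity, 1 / 7)  # only the lowest risk unflagged

  expect_error(scenario_fixed_fraction(rep(0.2, 10), outcomes, 0.3), "constant")
})

test_that("scenario A depends only on the risk ranking, not calibration", {
  set.seed(34)
  risks <- runif(200)
  outcomes <- rbinom(200, 1, risks)
  a <- scenario_fixed_fraction(risks, outcomes, 0.29)
  b <- scenario_fixed_fraction(plogis(5 * qlogis(risks) + 2), outcomes, 0.29)
  expect_identical(a$flags, b$flags)
  expect_equal(a$sensitivity, b$sensitivity)
})

test_that("scenario B attains the target sensitivity with a minimal flag set", {
  risks <- c(0.9, 0.6, 0.2, 0.85, 0.5, 0.4, 0.3, 0.1)
  outcomes <- c(1, 1, 1, 0, 0, 0, 0, 0)
  res <- scenario_fixed_sensitivity(risks, outcomes, 2 / 3)
  expect_equal(res$threshold, 0.6)
  expect_identical(res$flags, risks >= 0.6)
  expect_gte(res$sensitivity, 2 / 3)
  # minimality: one rank step fewer would miss the target
  stricter <- risks >= sort(risks[risks >= 0.6])[2]
  expect_lt(sum(stricter & outcomes) / 3, 2 / 3)

  full <- scenario_fixed_sensitivity(risks, outcomes, 1)
  expect_equal(full$threshold, 0.2)  # minimum case risk
  expect_true(all(full$flags[outcomes == 1]))

  expect_error(scenario_fixed_sensitivity(risks, rep(0, 8), 0.5), "no cases")
})

test_that("raising the sensitivity target never shrinks the flagged fraction", {
  set.seed(35)
  risks <- runif(400)
  outcomes <- rbinom(400, 1, risks^2)
  fr <- vapply(c(0.5, 0.6, 0.7, 0.8, 0.9, 1.0), function(s) {
    scenario_fixed_sensitivity(risks, outcomes, s)$flagged_fraction
  }, numeric(1))
  expect_true(all(diff(fr) >= 0))
})

test_that("sort-based scenario thresholds equal brute-force scans", {
  set.seed(36)
  for (i in 1:10) {
    n <- sample(50:500, 1)
    risks <- runif(n)  # distinct with probability 1
    outcomes <- rbinom(n, 1, 0.15)
    if (sum(outcomes) == 0) next
    a <- scenario_fixed_fraction(risks, outcomes, 0.29)
    expect_equal(a$threshold, scenario_a_bruteforce(risks, outcomes, 0.29))
    b <- scenario_fixed_sensitivity(risks, outcomes, 0.71)
    expect_equal(b$threshold, scenario_b_bruteforce(risks, outcomes, 0.71))
  }
})

test_that("reclassification tables cross-tabulate and marginalise exactly", {
  outcomes <- c(rep(1, 4), rep(0, 16))
  ref <- c(1, 1, 0, 0, rep(1, 4), rep(0, 12)) == 1
  model <- c(1, 1, 1, 0, rep(1, 3), rep(0, 13)) == 1  # +1 case, -1 non-case
  rt <- reclassification_table(ref, model, outcomes)
  expect_equal(sum(rt$counts), 20)
  expect_equal(rt$delta_cases_flagged, 1)
  expect_equal(rt$delta_noncases_flagged, -1)
  # marginals reproduce each classifier's 2x2
  expect_equal(sum(rt$counts[c("gdm_ref_high_model_high", "gdm_ref_high_model_low")]),
               sum(ref & outcomes == 1))
  expect_equal(sum(rt$counts[grep("model_high", names(rt$counts))]), sum(model))

  same <- reclassification_table(ref, ref, outcomes)
  offdiag <- same$counts[grep("high_model_low|low_model_high", names(same$counts))]
  expect_true(all(offdiag == 0))
})
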