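---
title: "Methods: prognostic models versus the single-risk-factor rule in first-trimester GDM screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prognostic models versus the single-risk-factor rule in first-trimester GDM screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The screening problem

Most European guidelines select women for a second-trimester oral glucose
tolerance test by a *single-risk-factor rule*: a woman is high-risk for
gestational diabetes mellitus (GDM) if at least one pre-specified factor is
present (BMI above 30 kg/m², a previous macrosomic child, a history of GDM, a
first-degree family history of diabetes, or an ethnicity with a high diabetes
prevalence). The alternative examined here is a *first-trimester logistic
prognostic model*: a weighted combination of the same kind of clinical
predictors that produces an individual risk, which can then be thresholded.
This package implements the full comparison pipeline — recalibration of four
published models, extension with the routinely measured first-trimester
random venous glucose, discrimination/calibration/decision-curve evaluation,
and two fixed-operating-point screening scenarios — on synthetic cohorts,
because the underlying patient-level cohort is not publicly available.

## Risk models and the reference rule

Each model is a declarative logistic equation
$\operatorname{logit} p = \beta_0 + \sum_j \beta_j f_j(x_j)$ with
transformations restricted to identity, natural log, and category
indicators. The four published models share ethnicity, BMI and history of
GDM; maternal age enters all but van Leeuwen 2010; family history of diabetes
enters Teede 2011 and van Leeuwen 2010; parity enters Nanda 2011 and van
Leeuwen 2010; history of macrosomia only Nanda 2011; and systolic blood
pressure only Gabbay-Benziv 2014. These predictor sets are enforced by the
config validator. The shipped coefficient file
(`inst/extdata/model_config_synthetic.yaml`) is **synthetic**: the original
full equations live in supplementary material we do not redistribute, so the
file carries plausible stand-in magnitudes with the correct predictor sets
and effect directions. Because every model is recalibrated on the analysis
cohort before use, downstream results depend on the models only through their
risk *ranking*, which makes the stand-in coefficients a faithful test bed for
the pipeline itself (they are not a reproduction of the original equations).

Two deliberate choices in the reference rule: the BMI cut-off is strict
(`bmi > 30`), following the methods-level definition of the rule rather than
a rounded abstract-style `>= 30` (both are available via `bmi_strict`); and
the "non-western, high diabetes prevalence" ethnicity set defaults to
`{asian, other}` because the guideline's list (Hindustani, Moroccan, Turkish,
Middle Eastern, Asian) does not map one-to-one onto the five cohort
categories — it is a configuration value, not a constant.

## The synthetic cohort generator

The generator is first-class, tested code; its defaults are the study
conditions every other stage is exercised under:

* age ~ N(30.8, 4.2²) years, SBP ~ N(115, 12²) mmHg;
* BMI and glucose are log-normal (both are right-skewed), with `meanlog`
  taken from the published medians (23.2 kg/m², 4.7 mmol/l) and `sdlog` from
  the quartile ratios (21.1–26.2, 4.4–5.1). Matching the median exactly and
  the IQR through its ratio reproduces the published quartiles to within
  ~0.3 units; a two-parameter family cannot hit all three order statistics
  exactly;
* height ~ N(168, 6.5²) cm, and weight is back-solved as
  $\mathrm{BMI}\cdot(\mathrm{height}/100)^2$, so the BMI identity holds by
  construction;
* ethnicity 91.0% Caucasian, education low/medium/high at the published
  counts, conception categories renormalised to sum to one, smoking 9.0%,
  family history of diabetes 14.6%, 44.5% nulliparous with a decaying
  parity distribution (37%, 14%, 3.5%, 1%);
* prior GDM (1.6%) and prior macrosomia (6.2%) are *overall* rates, realised
  only among parous women (rescaled by 1/P(parity>0)), so nulliparity
  implies no obstetric history;
* age, BMI, SBP and glucose share a Gaussian copula with a common latent
  correlation of 0.25 — a modest positive covariance without which glucose
  could not show realistic incremental value over BMI-based models.

The true outcome mechanism is a logistic model in BMI (0.18 per kg/m²), age
(0.05 per year), ln-glucose (6.0), history of GDM (2.2), family history
(0.9), and non-western ethnicity (asian 1.2, other 0.6), with the intercept
auto-tuned by bisection on the realised covariates so that the mean predicted
risk equals the target prevalence (default 4.9%). The ln-glucose weight is
calibrated to the *published* marginal discrimination of glucose alone
(c ≈ 0.68 in the source cohort): with `sdlog` 0.109, a coefficient near 6
gives $\Phi(\beta\sigma/\sqrt2)\approx0.68$. The remaining weights were
chosen once, for plausibility, and produce model c-statistics in the
published 0.72–0.80 band; the binary reference rule on these synthetic
cohorts is somewhat less sensitive than in the source population (≈0.56
versus 0.71), which the scenario analyses inherit through their
"from-reference" targets.

What the generator does **not** emulate: within-woman measurement error,
site/centre effects, non-random testing (the source cohort tested only
rule-positive or symptomatic women, which can only *under*-estimate model
performance there), and any covariate interactions. Passing tests therefore
demonstrate correctness of the pipeline under a known, well-behaved
data-generating process — not clinical performance on real data.

Missingness is injected explicitly (default: glucose 10%, SBP 5%, height and
weight 2%, education 3%, smoking 1% — free parameters, since the source
per-variable missingness table is not redistributed here) under MCAR or a
logistic MAR dependence whose intercept is solved so the marginal rate is
attained exactly in expectation.

## Multiple imputation and pooling

Imputation is chained equations with m = 10 (the analysis convention the
pipeline emulates), 10 sweeps per chain, each incomplete column modelled on
all other covariates plus the outcome. Draws are *proper*: continuous
columns use Bayesian linear regression (σ² from its scaled inverse
chi-square posterior, β from its normal posterior), binary columns a
logistic fit with a normal coefficient perturbation, categorical columns a
multinomial logit with perturbed coefficients. Plain fixed-MLE stochastic
draws would understate between-imputation variance and fail nominal
coverage of the pooled intervals, which the test suite checks directly
(95% ± 3% over 200 replicates at 20% MCAR). Predictive mean matching is
deliberately not used. Glucose is imputed on the log scale (positivity);
BMI is never regression-imputed — any two observed members of the
(BMI, height, weight) triple determine the third, and the identity is
restored after every sweep. Nulliparous rows have imputed obstetric history
forced to absent.

Pooling is Rubin's rules with no transformation of the estimates:
$\bar q = m^{-1}\sum q_i$, $T = W + (1+1/m)B$. Intervals use the
Barnard–Rubin small-sample degrees of freedom when a complete-data df is
supplied and a normal reference otherwise. C-statistics are pooled on the
raw scale with Hanley–McNeil within-imputation variances.

## Updating, evaluation, decision analysis

Recalibration fits outcome ~ linear predictor by logistic regression (glm,
IRLS, tolerance 1e-10, 100 iterations); divergence or |coefficient| > 40 is
reported as suspected separation instead of returning a silently divergent
fit. The glucose extension jointly refits outcome ~ {recalibrated LP,
ln glucose}; its added value is a likelihood-ratio chi-square with 1 df.
Because no standard combination rule for LR tests across imputations is
asserted by the emulated analysis, the pipeline reports the per-imputation
statistics together with their median and the fraction significant at 0.05,
clearly labelled as such, rather than a single pooled p-value.

Updating coefficients are pooled across imputations *before* scoring, so one
updated equation (as a clinician would receive) is evaluated per model;
c-statistics are then computed per imputation and Rubin-pooled.

The c-statistic uses the midrank identity (exactly the all-pairs count with
ties at one half, verified against brute force). Calibration uses ten
equal-frequency bins on the stacked imputations plus a fixed-span moving
average; ties at bin edges are broken by stable rank, so duplicated risk
values may straddle bins. Net benefit at threshold $p_t$ is
$TP/n - (FP/n)\,p_t/(1-p_t)$ on a default grid 0.005–0.30 (step 0.005),
covering the informative 2–12% region; the binary reference method
contributes its fixed flags at every threshold (it has no risk scale), which
is the only coherent way to place a rule on a decision curve. Scenario A
flags the top-k risks for k = ⌊target·n⌋ (stable tie-break, attained
fraction reported); scenario B takes the largest threshold whose sensitivity
reaches the target, i.e. the smallest flag set that still detects the target
share of cases. Scenario metrics are computed per imputation and averaged.

## Problem sizes and numerical choices

The shipped analyses and tests run at the emulated study size (n = 3723,
m = 10) for the end-to-end stages, n = 50,000–100,000 for marginal/prevalence
recovery, 200 replicates at n = 5,000 for recalibration coverage, and 200
replicates at n = 400 for imputation coverage — sizes at which the binomial
Monte-Carlo error bands used by the tests are informative. Tolerances are
3 (occasionally 3.5–4) standard errors for stochastic checks and 1e-12 for
algebraic identities. Degenerate inputs (constant linear predictors,
single-class outcomes, empty classifier cells, non-positive glucose,
entirely-missing columns) raise informative errors rather than propagating
NaN.

## Known limitations

* The coefficient file is a synthetic stand-in; absolute risks from the
  *original* (un-recalibrated) published equations are out of reach here.
* LR-test pooling across imputations reports medians, not a D1/D2-style
  combined test.
* The generator draws covariates from a single copula family; it cannot
  falsify model behaviour under covariate structures it does not contain.
* The reference method's operating point on synthetic cohorts differs from
  the published one (sensitivity ≈ 0.56 versus 0.71), so scenario targets
  differ correspondingly; all comparisons are internally consistent.
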