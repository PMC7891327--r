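# SYNTHETIC model-coefficient configuration.
#
# The predictor set of each published first-trimester GDM model follows the
# published descriptions exactly (ethnicity, BMI and history of GDM in all
# four; age in all but van Leeuwen 2010; family history of diabetes in Teede
# 2011 and van Leeuwen 2010; parity in Nanda 2011 and van Leeuwen 2010;
# history of macrosomia only in Nanda 2011; systolic blood pressure only in
# Gabbay-Benziv 2014). The COEFFICIENT VALUES are synthetic stand-ins with
# plausible effect directions and magnitudes, not a transcription of the
# original equations; every model is recalibrated (slope + intercept) on the
# analysis cohort before use, so only the relative weighting of predictors
# matters downstream.
models:
  - name: gabbay_benziv_2014
    intercept: -9.5
    terms:
      - {predictor: age_years, transform: identity, coefficient: 0.05}
      - {predictor: bmi, transform: identity, coefficient: 0.10}
      - {predictor: sbp_mmhg, transform: identity, coefficient: 0.01}
      - {predictor: history_gdm, transform: identity, coefficient: 1.8}
      - {predictor: ethnicity, transform: indicator, level: african, coefficient: 0.5}
      - {predictor: ethnicity, transform: indicator, level: asian, coefficient: 0.9}
      - {predictor: ethnicity, transform: indicator, level: other, coefficient: 0.5}
  - name: nanda_2011
    intercept: -8.4
    terms:
      - {predictor: age_years, transform: identity, coefficient: 0.06}
      - {predictor: bmi, transform: identity, coefficient: 0.09}
      - {predictor: history_gdm, transform: identity, coefficient: 2.0}
      - {predictor: history_macrosomia, transform: identity, coefficient: 0.7}
      - {predictor: parity, transform: identity, coefficient: 0.15}
      - {predictor: ethnicity, transform: indicator, level: african, coefficient: 0.4}
      - {predictor: ethnicity, transform: indicator, level: asian, coefficient: 1.0}
      - {predictor: ethnicity, transform: indicator, level: mixed, coefficient: 0.3}
      - {predictor: ethnicity, transform: indicator, level: other, coefficient: 0.5}
  - name: teede_2011
    intercept: -8.6
    terms:
      - {predictor: age_years, transform: identity, coefficient: 0.068}
      - {predictor: bmi, transform: identity, coefficient: 0.093}
      - {predictor: family_history_dm, transform: identity, coefficient: 0.74}
      - {predictor: history_gdm, transform: identity, coefficient: 2.1}
      - {predictor: ethnicity, transform: indicator, level: asian, coefficient: 1.0}
      - {predictor: ethnicity, transform: indicator, level: other, coefficient: 0.6}
  - name: van_leeuwen_2010
    intercept: -6.1
    terms:
      - {predictor: bmi, transform: identity, coefficient: 0.08}
      - {predictor: history_gdm, transform: identity, coefficient: 2.3}
      - {predictor: family_history_dm, transform: identity, coefficient: 0.7}
      - {predictor: parity, transform: identity, coefficient: 0.10}
      - {predictor: ethnicity, transform: indicator, level: asian, coefficient: 1.2}
      - {predictor: ethnicity, transform: indicator, level: other, coefficient: 0.5}
reference_method:
  bmi_cutoff: 30
  bmi_strict: true
  high_prevalence_ethnicities: [asian, other]
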