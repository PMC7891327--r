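#!/usr/bin/env Rscript
# Stage 1 — simulate the study cohort.
#
# Generates a synthetic maternal cohort of 3723 first-trimester pregnancies
# whose marginals match the published cohort description (age 30.8 +/- 4.2 y,
# BMI median 23.2, glucose median 4.7 mmol/l, 91% Caucasian, 44.5%
# nulliparous, GDM prevalence ~4.9%), then injects realistic missingness
# (mostly in glucose and blood pressure) so the imputation stage has work to
# do. Writes results/cohort.csv.

library(gdmscreen)

seed <- 1L
dir.create("results", showWarnings = FALSE)

cohort <- generate_cohort(generator_config(seed = seed))
cat(sprintf("simulated %d pregnancies; GDM prevalence %.1f%%\n",
            nrow(cohort), 100 * mean(cohort$gdm)))

holey <- apply_missingness(cohort, missingness_config(seed = seed + 1L))
cat(sprintf("injected missingness: %d incomplete cells across %d columns\n",
            sum(is.na(holey)), sum(colSums(is.na(holey)) > 0)))

write_cohort_csv(holey, "results/cohort.csv")
cat("wrote results/cohort.csv\n")
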