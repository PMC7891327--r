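#!/usr/bin/env Rscript
# Stage 5 — decision curves, fixed-operating-point scenarios and
# reclassification.
#
# Reads the report written by stage 4, prints the scenario table (A: flagged
# fraction held at the reference method's; B: sensitivity held at the
# reference method's), writes results/decision_curves.csv and, when ggplot2
# is available, a decision-curve figure.

library(gdmscreen)

report <- jsonlite::read_json("results/report/report.json")
dc <- utils::read.csv("results/report/decision_curves.csv",
                      stringsAsFactors = FALSE)
utils::write.csv(dc, "results/decision_curves.csv", row.names = FALSE)

cat(sprintf("scenario targets: flagged %.1f%%, sensitivity %.1f%%\n",
            100 * report$scenario_targets$fraction,
            100 * report$scenario_targets$sensitivity))
for (nm in names(report$scenarios)) {
  s <- report$scenarios[[nm]]
  cat(sprintf("%-20s A: sens %.1f%% at %.1f%% flagged | B: %.1f%% flagged at sens %.1f%%\n",
              nm, 100 * s$A$sensitivity, 100 * s$A$flagged_fraction,
              100 * s$B$flagged_fraction, 100 * s$B$sensitivity))
}
cat(sprintf("best model (%s) vs reference: %+.1f cases flagged, %+.1f non-cases flagged\n",
            report$best_model, report$reclassification$delta_cases_flagged,
            report$reclassification$delta_noncases_flagged))

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  p <- ggplot(subset(dc, net_benefit > -0.01),
              aes(threshold, net_benefit, colour = strategy)) +
    geom_line() +
    labs(x = "threshold probability", y = "net benefit",
         title = "Decision curves: reference method vs updated models") +
    theme_minimal()
  ggsave("results/decision_curves.png", p, width = 7, height = 4.5, dpi = 150)
  cat("wrote results/decision_curves.png\n")
}
cat("wrote results/decision_curves.csv\n")
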