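#!/usr/bin/env Rscript
# Step 3 — model development.
# Runs the dual-outcome pipeline over the modelled factor subsets (three
# conditions for the 10% outcome, the same three plus CHESS acuity for the
# 20% outcome): truth table at the highest workable consistency cutoff,
# parsimonious minimization, 15% unique-coverage pruning, selection
# criteria, and the necessity/sufficiency sweep. Writes the full report in
# both JSON and text form.

suppressPackageStartupMessages(library(csqca))
dir.create("results", showWarnings = FALSE)

report <- run_pipeline(list(
  table = "optimistic",
  outcomes = c("decline10", "decline20"),
  derive_outcomes = list(pre = "pre_rate", during = "during_rate",
                         thresholds = c(0.10, 0.20)),
  factor_subsets = list(
    decline10 = c("don_turnover", "support", "low_baseline"),
    decline20 = c("don_turnover", "support", "low_baseline", "chess"))))

writeLines(render_report(report, "json"), "results/03_models.json")
txt <- render_report(report, "text")
writeLines(txt, "results/03_models.txt")
cat(txt)
cat("\nwrote results/03_models.json and results/03_models.txt\n")
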