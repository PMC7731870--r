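#!/usr/bin/env Rscript
# Step 4 — synthetic validation.
# Checks the engine on data with a known answer: tables planted with the
# two-path model A + B*~C (the same shape as the published solutions), the
# original factor mix (six dichotomous, five multivalue factors, 19-24
# cases). Noiseless tables with full configuration coverage must be
# recovered exactly; recovery should degrade as outcome-flip noise grows.

suppressPackageStartupMessages(library(csqca))
dir.create("results", showWarnings = FALSE)

planted <- dnf_model(list(conjunction(A = 1), conjunction(B = 1, C = 0)))

rows <- lapply(c(0, 0.1, 0.2), function(eps) {
  spec <- generator_spec(planted, n_cases = 24, config_sampling = "balanced",
                         outcome_flip_prob = eps, seed = 2024)
  res <- recovery_experiment(spec, n_reps = 100)
  data.frame(flip_prob = eps,
             recovery_rate = res$recovery_rate,
             se = res$se,
             mean_threshold = mean(res$replicates$threshold, na.rm = TRUE))
})
tab <- do.call(rbind, rows)
write.csv(tab, "results/04_recovery.csv", row.names = FALSE, quote = FALSE)
print(tab, row.names = FALSE, digits = 3)

stopifnot(tab$recovery_rate[1] == 1)
cat("\nnoiseless full-coverage recovery is exact; recovery degrades with flip noise\n")
cat("wrote results/04_recovery.csv\n")
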