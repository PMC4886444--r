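#!/usr/bin/env Rscript

# Step 4: Monte Carlo uncertainty analysis.
#
# Samples elasticities, consumption means, the energy-to-weight constant
# and the relative risks from their uncertainty distributions, re-runs the
# pipeline per draw, and reports 95% uncertainty intervals (2.5th and
# 97.5th percentiles) around the base-case point estimates.

suppressPackageStartupMessages(library(ssbstroke))

bundle <- read_bundle(file.path("results", "inputs"))
mc <- mc_config(n_draws = 2000, seed = 7L)
ui <- run_monte_carlo(bundle, tax_scenario(), mc)

out <- file.path("results", "uncertainty.csv")
write.csv(ui$table, out, row.names = FALSE)
cat("wrote", out, "(", ui$n_failed, "failed draws )\n")
print(ui$table, digits = 5)
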