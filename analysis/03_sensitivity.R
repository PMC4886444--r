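#!/usr/bin/env Rscript

# Step 3: deterministic one-way sensitivity analysis.
#
# Re-runs the full pipeline varying one assumption at a time around the
# base case: tax rate, discount rate, portion size, health-care costs,
# disability burden, secular BMI trend, pass-on rate, and a conservative
# own-price elasticity. Writes the grid as a CSV.

suppressPackageStartupMessages(library(ssbstroke))

bundle <- read_bundle(file.path("results", "inputs"))
grid <- sensitivity_grid(bundle, base = tax_scenario())

out <- file.path("results", "sensitivity_grid.csv")
dir.create(dirname(out), recursive = TRUE, showWarnings = FALSE)
write.csv(grid, out, row.names = FALSE)
cat("wrote", out, "(", nrow(grid), "rows )\n")
print(grid, digits = 4)
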