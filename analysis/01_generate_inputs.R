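#!/usr/bin/env Rscript

# Step 1: generate and validate the synthetic input bundle.
#
# The bundle emulates the structure of the study inputs — beverage
# consumption by age and sex, BMI summary statistics with two survey waves,
# stroke epidemiology, relative risks and unit costs — from a single seed.
# All later steps read the bundle back from disk, so the whole workflow is
# reproducible from this script alone.

suppressPackageStartupMessages(library(ssbstroke))

seed <- 1L
out_dir <- file.path("results", "inputs")

bundle <- generate_bundle(synthetic_config(seed = seed))

v <- validate_bundle(bundle)
print(v)
if (!v$ok) stop("input bundle failed validation; see violations above")

write_bundle(bundle, out_dir)
cat("bundle written to", out_dir, "\n")
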