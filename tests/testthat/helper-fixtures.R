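# Shared fixtures: one default synthetic bundle reused across test files.
fixture_bundle <- function() {
  if (is.null(.fixture_env$bundle)) {
    .fixture_env$bundle <- generate_bundle(synthetic_config(seed = 42))
  }
  .fixture_env$bundle
}
.fixture_env <- new.env(parent = emptyenv())

# Monte Carlo standard error of a sample mean
mc_se <- function(x) stats::sd(x) / sqrt(length(x))
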