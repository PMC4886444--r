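zero_sd_bundle <- function(b = fixture_bundle()) {
  b$elasticities$sd <- 0
  b$consumption$intake_se <- 0
  b$rr$log_se <- 0
  b$params$kj_per_kg_sd <- 0
  b
}

test_that("parameter draws are reproducible and respect their bounds", {
  b <- fixture_bundle()
  P <- ssbstroke:::compile_params(b)
  mc <- mc_config(n_draws = 5, seed = 9)
  d1 <- draw_parameters(P, mc, 3L)
  d2 <- draw_parameters(P, mc, 3L)
  expect_identical(d1, d2)
  d3 <- draw_parameters(P, mc, 4L)
  expect_false(identical(d1$eps, d3$eps))
  expect_true(all(d1$Q >= 0))
  expect_gt(d1$k, 0)
  expect_true(all(d1$rr > 0))
  # all SDs zero: every draw equals the means
  P0 <- ssbstroke:::compile_params(zero_sd_bundle())
  dz <- draw_parameters(P0, mc, 1L)
  expect_equal(unname(dz$eps), unname(P0$eps), tolerance = 0)
  expect_equal(dz$Q, P0$Q, tolerance = 0)
  expect_identical(dz$k, P0$k)
  expect_equal(dz$rr, P0$rr, tolerance = 0)
})

test_that("conversion-factor draws reproduce the stated moments", {
  b <- fixture_bundle()
  P <- ssbstroke:::compile_params(b)
  expect_identical(P$k, 94)
  expect_identical(P$k_sd, 2.96)
  set.seed(701)
  x <- ssbstroke:::rnorm_trunc(1e5, rep(94, 1e5), rep(2.96, 1e5))
  expect_lt(abs(mean(x) - 94), 3 * 2.96 / sqrt(1e5))
  expect_lt(abs(sd(x) - 2.96), 3 * 2.96 / sqrt(2 * (1e5 - 1)))
})

test_that("truncation gives up after too many rejected resamples", {
  expect_error(
    ssbstroke:::rnorm_trunc(5, rep(-100, 5), rep(0.1, 5), lo = 0,
                            max_rounds = 50L),
    "resampling")
})

test_that("a zero-SD configuration collapses the uncertainty interval", {
  b0 <- zero_sd_bundle()
  ui <- run_monte_carlo(b0, tax_scenario(), mc_config(n_draws = 10, seed = 2))
  expect_equal(ui$table$lo, ui$table$point, tolerance = 1e-9)
  expect_equal(ui$table$hi, ui$table$point, tolerance = 1e-9)
  expect_equal(ui$table$mean, ui$table$point, tolerance = 1e-9)
  expect_identical(ui$n_failed, 0L)
})

test_that("uncertainty intervals are ordered and widen with parameter SDs", {
  b <- fixture_bundle()
  sc <- tax_scenario()
  ui1 <- run_monte_carlo(b, sc, mc_config(n_draws = 60, seed = 5))
  expect_true(all(ui1$table$lo <= ui1$table$mean + 1e-9))
  expect_true(all(ui1$table$mean <= ui1$table$hi + 1e-9))
  b2 <- b
  b2$elasticities$sd <- 3 * b2$elasticities$sd
  ui2 <- run_monte_carlo(b2, sc, mc_config(n_draws = 60, seed = 5))
  w1 <- ui1$table$hi - ui1$table$lo
  w2 <- ui2$table$hi - ui2$table$lo
  expect_true(all(w2 >= w1 * 0.99))
  expect_gt(w2[w1 > 0][1L] / w1[w1 > 0][1L], 1.2)
})

test_that("the sensitivity grid is deterministic and Table-2 shaped", {
  b <- fixture_bundle()
  g1 <- sensitivity_grid(b)
  g2 <- sensitivity_grid(b)
  expect_identical(g1, g2)
  expect_identical(nrow(g1), 27L)
  expect_identical(
    as.vector(table(g1$parameter)[unique(g1$parameter)]),
    c(3L, 4L, 4L, 5L, 3L, 4L, 3L, 1L))
  # the base case appears identically in every block that contains it
  base_rows <- g1[(g1$parameter == "tax_rate" & g1$level == "20%") |
                    (g1$parameter == "discount_rate" & g1$level == "0%") |
                    (g1$parameter == "portion_size" & g1$level == "330 ml") |
                    (g1$parameter == "cost_scale" & g1$level == "100%") |
                    (g1$parameter == "pass_on_rate" & g1$level == "100%"), ]
  for (col in c("incidence_change", "dalys_averted",
                "prevalence_change_final_year", "costs_change_zar")) {
    expect_equal(max(base_rows[[col]]) - min(base_rows[[col]]), 0,
                 tolerance = 1e-9)
  }
})
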