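const_rates <- function(i = 0.02, f = 0.15, d28 = 0.3, m = 0.01,
                        bg = 0.05) {
  function(age) list(incidence = i, case_fatality = f, d28 = d28,
                     mortality_all = m, pyld_bg = bg)
}

test_that("sector weighting of costs matches the two quoted parameters", {
  expect_equal(weighted_cost(100), 75.4, tolerance = 1e-12)
  expect_equal(weighted_cost(100, 0.18, 0.70), 0.18 * 100 + 0.82 * 70,
               tolerance = 1e-12)
  expect_identical(weighted_cost(100, private_share = 1), 100)
  expect_equal(weighted_cost(250, 0.4, 1), 250, tolerance = 1e-12)
  expect_error(weighted_cost(100, private_share = 1.5), "private_share")
  expect_error(weighted_cost(100, public_private_ratio = 0), "ratio")
})

test_that("one annual cycle reproduces hand-computed flows", {
  st <- disease_step(S = 1000, C = 0, i = 0.01, f = 0.2, d28 = 1 / 3,
                     m_other = 0)
  expect_equal(st$new_cases, 1000 * (1 - exp(-0.01)), tolerance = 1e-12)
  expect_equal(st$new_cases, 9.9502, tolerance = 1e-4)
  expect_equal(st$acute_deaths, 1000 * (1 - exp(-0.01)) / 3,
               tolerance = 1e-12)
  expect_equal(st$acute_deaths, 3.3167, tolerance = 1e-4)
  expect_equal(st$C, 1000 * (1 - exp(-0.01)) * 2 / 3, tolerance = 1e-12)
  # zero incidence: the prevalent pool only decays
  st0 <- disease_step(S = 500, C = 100, i = 0, f = 0.2, d28 = 0.3,
                      m_other = 0.05)
  expect_identical(st0$new_cases, 0)
  expect_equal(st0$case_deaths, 100 * (1 - exp(-0.2)), tolerance = 1e-12)
  # full elimination via the PIF equals zero incidence
  st1 <- disease_step(S = 500, C = 100, i = 0.3, f = 0.2, d28 = 0.3,
                      m_other = 0.05, pif = 1)
  expect_equal(st1, st0, tolerance = 1e-15)
  expect_error(disease_step(100, 0, i = 0.1, f = 0.1, d28 = 0.3,
                            m_other = 0.1, pif = 2), ">= 0")
})

test_that("persons are conserved in every randomized cohort-year", {
  set.seed(601)
  for (rep in 1:100) {
    S <- runif(1, 10, 1e6)
    C <- runif(1, 0, S / 4)
    st <- disease_step(S, C, i = runif(1, 0, 0.5), f = runif(1, 0, 1),
                       d28 = runif(1), m_other = runif(1, 0, 1),
                       pif = runif(1, -0.5, 1))
    expect_equal(st$S + st$C + st$total_deaths, S + C,
                 tolerance = 1e-9)
  }
})

test_that("a cohort simulation matches an independently unrolled computation", {
  # hand-unrolled difference equations, written as a plain scalar loop
  pop <- 1000; prev <- 0.05
  i <- 0.02; f <- 0.15; d28 <- 0.3; m <- 0.01; pif <- 0.1
  dw <- 0.28; bg <- 0.05; wc <- 100
  S <- pop * (1 - prev); C <- pop * prev
  oracle <- NULL
  for (t in 1:5) {
    nc <- S * (1 - exp(-i * (1 - pif)))
    ad <- nc * d28
    en <- nc - ad
    cd <- C * (1 - exp(-f))
    s1 <- S - nc
    c1 <- C - cd + en
    os <- s1 * (1 - exp(-m))
    oc <- c1 * (1 - exp(-m))
    s2 <- s1 - os
    c2 <- c1 - oc
    pm <- (C + c2) / 2
    ly <- (S + C + s2 + c2) / 2
    oracle <- rbind(oracle, data.frame(
      year = t, new_cases = nc, acute_deaths = ad, case_deaths = cd,
      stroke_deaths = ad + cd, total_deaths = ad + cd + os + oc,
      S_end = s2, C_end = c2, prevalent_mid = pm, life_years = ly,
      halys = ly * (1 - bg) - pm * dw, costs = pm * wc))
    S <- s2; C <- c2
  }
  sim <- run_cohort(pop, prev, entry_age = 40, const_rates(i, f, d28, m, bg),
                    pif = pif, n_years = 5, dw = dw,
                    cost_per_case_year = wc)
  for (col in names(oracle)[-1]) {
    expect_equal(sim[[col]], oracle[[col]], tolerance = 1e-9, label = col)
  }
})

test_that("degenerate cohort settings have their structural consequences", {
  # d28 = 1: incident cases never enter the prevalent pool
  sim <- run_cohort(1000, 0, 30, const_rates(i = 0.05, d28 = 1), n_years = 10)
  expect_true(all(sim$C_end == 0))
  expect_true(all(sim$prevalent_mid == 0))
  expect_gt(sum(sim$stroke_deaths), 0)
  # alive counts never increase
  sim2 <- run_cohort(1000, 0.1, 30, const_rates(), n_years = 30)
  alive <- sim2$S_end + sim2$C_end
  expect_true(all(diff(alive) <= 0))
  expect_true(all(alive >= 0))
  expect_error(run_cohort(100, 0, entry_age = 100, const_rates()),
               "age 100")
})

test_that("discounting is anchored at the first model year", {
  expect_identical(discount_series(c(10, 20, 30), 0), c(10, 20, 30))
  expect_equal(discount_series(c(0, 100), 0.03)[2L], 97.0874,
               tolerance = 1e-4)
  expect_equal(discount_series(c(0, 100), 0.03)[2L], 100 / 1.03,
               tolerance = 1e-12)
  x <- runif(20, 0, 100)
  expect_lt(sum(discount_series(x, 0.05)), sum(x))
  expect_error(discount_series(1:3, -0.01), "rate")
})
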