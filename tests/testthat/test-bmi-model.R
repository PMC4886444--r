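test_that("the equilibrium energy-balance conversion is exact", {
  expect_identical(equilibrium_weight_change(-94, 94), -1)
  expect_identical(equilibrium_weight_change(0), 0)
  expect_equal(equilibrium_weight_change(-36), -36 / 94, tolerance = 1e-12)
  expect_error(equilibrium_weight_change(10, k = 0), "k must be > 0")
  expect_error(equilibrium_weight_change(10, k = -5), "k must be > 0")
})

test_that("weight changes convert to BMI changes through height squared", {
  expect_equal(weight_to_bmi_change(-1, 1.6), -0.390625, tolerance = 1e-12)
  expect_identical(weight_to_bmi_change(0, 1.7), 0)
  expect_identical(weight_to_bmi_change(-2.5, 1), -2.5)
  expect_error(weight_to_bmi_change(1, 0), "height")
})

test_that("log-normal moment fitting matches the closed form and round-trips", {
  ln <- fit_lognormal(25, 5)
  expect_equal(ln$sigma, sqrt(log(1 + (5 / 25)^2)), tolerance = 1e-12)
  expect_equal(ln$sigma, 0.1980422, tolerance = 1e-6)
  expect_equal(ln$mu, 3.1992648, tolerance = 1e-6)
  # mean = exp(0.5) with sigma = 1 implies mu = 0
  m <- exp(0.5)
  s <- m * sqrt(exp(1) - 1)
  ln2 <- fit_lognormal(m, s)
  expect_equal(ln2$mu, 0, tolerance = 1e-12)
  expect_equal(ln2$sigma, 1, tolerance = 1e-12)
  # algebraic round-trip
  for (mm in c(18, 25, 34)) {
    for (ss in c(2, 5, 8)) {
      ln3 <- fit_lognormal(mm, ss)
      mo <- lognormal_moments(ln3$mu, ln3$sigma)
      expect_equal(mo$mean, mm, tolerance = 1e-9)
      expect_equal(mo$sd, ss, tolerance = 1e-9)
    }
  }
  expect_error(fit_lognormal(-1, 5), "positive")
  expect_error(fit_lognormal(25, 0), "positive")
})

test_that("sampling from the fitted log-normal recovers the moments", {
  set.seed(401)
  ln <- fit_lognormal(27, 6)
  x <- rlnorm(1e6, ln$mu, ln$sigma)
  expect_lt(abs(mean(x) - 27), 3 * sd(x) / sqrt(length(x)))
  # SE of the SD of a log-normal is wider than the normal formula; use a
  # conservative 4x normal-theory bound
  expect_lt(abs(sd(x) - 6), 4 * 6 / sqrt(2 * (length(x) - 1)) * 3)
})

test_that("distribution shifts follow the SD-mean relation and invert", {
  d0 <- bmi_distribution(27, 5, "x")
  expect_equal(shift_distribution(d0, 0), d0)
  d1 <- shift_distribution(d0, -0.39, sd_relation(0))
  expect_equal(d1$mean, 27 - 0.39)
  expect_equal(d1$sd, 5)
  d2 <- shift_distribution(d0, -0.4, sd_relation(0.5))
  expect_equal(d2$sd, 5 - 0.2, tolerance = 1e-12)
  # shift then unshift returns the original distribution
  d3 <- shift_distribution(d2, +0.4, sd_relation(0.5))
  expect_equal(d3$mean, d0$mean, tolerance = 1e-12)
  expect_equal(d3$sd, d0$sd, tolerance = 1e-12)
  expect_equal(d3$mu, d0$mu, tolerance = 1e-12)
  # trend accrues linearly with year
  d4 <- shift_distribution(d0, 0, sd_relation(0.3), trend = 0.1, year = 5)
  expect_equal(d4$mean, 27.5, tolerance = 1e-12)
  expect_equal(d4$sd, 5 + 0.3 * 0.5, tolerance = 1e-12)
  expect_error(shift_distribution(d0, -40), "degenerate")
  expect_error(shift_distribution(d0, -8, sd_relation(0.7)), "degenerate")
})

test_that("the SD-vs-mean slope is recovered from two waves", {
  b <- fixture_bundle()
  slope <- estimate_sd_slope(b$bmi_waves)
  expect_equal(slope, b$manifest$true_sd_slope, tolerance = 0.05)
  expect_identical(b$params$sd_slope, slope)
  # exact recovery in the noise-free case
  waves <- data.frame(mean_wave1 = c(24, 26, 28), sd_wave1 = c(4, 4.5, 5),
                      mean_wave2 = c(24.5, 26.8, 28.2),
                      sd_wave2 = c(4, 4.5, 5) + 0.6 * c(0.5, 0.8, 0.2))
  expect_equal(estimate_sd_slope(waves), 0.6, tolerance = 1e-12)
})
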