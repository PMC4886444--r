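mini_consumption <- function(ssb = 184, juice = 0, milk = 0, diet = 0) {
  data.frame(age_group = "15-19", sex = "male",
             beverage = c("ssb", "juice", "milk", "diet"),
             intake_ml = c(ssb, juice, milk, diet),
             intake_se = 0, stringsAsFactors = FALSE)
}

eps_table <- function(ssb = -1.299, juice = 0, milk = 0, diet = 0) {
  data.frame(beverage = c("ssb", "juice", "milk", "diet"),
             elasticity = c(ssb, juice, milk, diet), sd = 0,
             stringsAsFactors = FALSE)
}

test_that("the tax maps to the retail price change via the pass-on rate", {
  expect_identical(effective_price_change(tax_scenario(0.20, 1.0)), 0.20)
  expect_equal(effective_price_change(tax_scenario(0.20, 0.8)), 0.16,
               tolerance = 1e-12)
  expect_identical(effective_price_change(tax_scenario(0, 0.5)), 0)
  expect_error(tax_scenario(pass_on_rate = 1.2), "pass_on_rate")
  expect_error(tax_scenario(tax_rate = -0.1), "tax_rate")
})

test_that("elasticities reproduce hand-computed consumption changes", {
  dq <- consumption_change(mini_consumption(), eps_table(), dpp = 0.20)
  expect_equal(dq$delta_ml[dq$beverage == "ssb"], 184 * (-1.299) * 0.20,
               tolerance = 1e-9)
  # zero elasticity and zero price change both null the response
  expect_true(all(consumption_change(mini_consumption(300, 100, 50, 20),
                                     eps_table(0, 0, 0, 0),
                                     0.2)$delta_ml == 0))
  expect_true(all(consumption_change(mini_consumption(300, 100, 50, 20),
                                     eps_table(), 0)$delta_ml == 0))
  # linearity in the price change
  d1 <- consumption_change(mini_consumption(), eps_table(), 0.1)$delta_ml
  d2 <- consumption_change(mini_consumption(), eps_table(), 0.2)$delta_ml
  expect_equal(2 * d1, d2, tolerance = 1e-12)
  # iso-elastic alternative
  di <- consumption_change(mini_consumption(), eps_table(), 0.2,
                           form = "isoelastic")
  expect_equal(di$delta_ml[di$beverage == "ssb"],
               184 * (1.2^(-1.299) - 1), tolerance = 1e-9)
  # at dp/p = 0.2 the two forms differ by roughly 10%
  lin <- 184 * (-1.299) * 0.2
  expect_gt(abs((di$delta_ml[di$beverage == "ssb"] - lin) / lin), 0.05)
  expect_lt(abs((di$delta_ml[di$beverage == "ssb"] - lin) / lin), 0.20)
  expect_error(
    consumption_change(mini_consumption(),
                       eps_table()[eps_table()$beverage != "milk", ], 0.2),
    "milk")
})

test_that("energy changes sum beverage contributions at their densities", {
  dens <- default_energy_densities()
  dq <- consumption_change(mini_consumption(), eps_table(), 0.20)
  de <- net_energy_change(dq, dens)
  expect_equal(de$delta_kj, 184 * (-1.299) * 0.20 * 1800 / 1000,
               tolerance = 1e-9)
  # substitution adds energy back: -47.8032 ml SSB + 10 ml juice
  dq2 <- dq
  dq2$delta_ml[dq2$beverage == "ssb"] <- -47.8032
  dq2$delta_ml[dq2$beverage == "juice"] <- 10
  de2 <- net_energy_change(dq2, dens)
  expect_equal(de2$delta_kj, -47.8032 * 1.8 + 10 * 1.34, tolerance = 1e-9)
  # diet drinks carry zero energy density
  dq3 <- dq
  dq3$delta_ml <- ifelse(dq3$beverage == "diet", 100, 0)
  expect_equal(net_energy_change(dq3, dens)$delta_kj, 0)
  # all-zero change gives zero energy
  dq4 <- dq
  dq4$delta_ml <- 0
  expect_equal(net_energy_change(dq4, dens)$delta_kj, 0)
})

test_that("substitutes return less energy than SSBs lose on default inputs", {
  b <- fixture_bundle()
  dq <- consumption_change(b$consumption, b$elasticities, 0.20)
  de_by_bev <- sapply(c("ssb", "juice", "milk", "diet"), function(bev) {
    sub <- dq[dq$beverage == bev, ]
    d <- b$energy_densities$density_kj_per_l[
      b$energy_densities$beverage == bev]
    sum(sub$delta_ml * d / 1000)
  })
  expect_lt(de_by_bev[["ssb"]], 0)
  added <- sum(de_by_bev[c("juice", "milk", "diet")])
  expect_gt(added, 0)
  expect_lt(added, abs(de_by_bev[["ssb"]]))
  # net change negative in every stratum
  de <- net_energy_change(dq, b$energy_densities)
  expect_true(all(de$delta_kj < 0))
})
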