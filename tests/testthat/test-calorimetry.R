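test_that("baseline air with no animal yields zero rates", {
  s <- gas_sample(feo2 = 0.2095, feco2 = 0, ph2o = 0, fr = 500,
                  mode = "push_chamber")
  r <- gas_exchange_rates(s)
  expect_equal(unlist(r[c("vo2", "vco2", "ewl")]),
               c(vo2 = 0, vco2 = 0, ewl = 0))
  expect_false(r$flag)
})

test_that("mass-balance inversion recovers known rates in every mode", {
  cases <- list(
    list(mode = "push_chamber", vo2 = 0.70, vco2 = 0.60, ewl = 1.5,
         fr = 500),
    list(mode = "pull_mask", vo2 = 1.0, vco2 = 0.85, ewl = 3.0,
         fr = 500),
    list(mode = "pull_chamber", vo2 = 0, vco2 = 0, ewl = 1.0,
         fr = 200))
  for (cc in cases) {
    ex <- simulate_excurrent(cc$vo2, cc$vco2, cc$ewl, cc$fr,
                             mode = cc$mode)
    r <- gas_exchange_rates(gas_sample(ex$feo2, ex$feco2, ex$ph2o,
                                       cc$fr, mode = cc$mode))
    expect_equal(r$vo2, cc$vo2, tolerance = 1e-6)
    expect_equal(r$vco2, cc$vco2, tolerance = 1e-6)
    expect_equal(r$ewl, cc$ewl, tolerance = 1e-6)
  }
})

test_that("inversion stays exact with humid incurrent air and CO2 bleed", {
  ex <- simulate_excurrent(0.9, 0.75, 2.0, 400, mode = "pull_mask",
                           fio2 = 0.2090, fico2 = 5e-4, pih2o = 0.4)
  r <- gas_exchange_rates(gas_sample(ex$feo2, ex$feco2, ex$ph2o, 400,
                                     mode = "pull_mask", fio2 = 0.2090,
                                     fico2 = 5e-4, pih2o = 0.4))
  expect_equal(r$vo2, 0.9, tolerance = 1e-9)
  expect_equal(r$vco2, 0.75, tolerance = 1e-9)
  expect_equal(r$ewl, 2.0, tolerance = 1e-9)
})

test_that("non-physical inputs error; noisy negatives are zeroed or flagged", {
  expect_error(gas_sample(0.21, 0, ph2o = 110, fr = 500,
                          mode = "pull_mask"),
               "barometric")
  expect_error(gas_sample(1.2, 0, 1, 500, mode = "push_chamber"),
               "fraction")
  expect_error(gas_sample(0.2, 0, 1, fr = -5, mode = "push_chamber"),
               "flow")
  # tiny apparent O2 production: zeroed with a warning, not flagged
  ex <- simulate_excurrent(0.002, 0.004, 0, 500, mode = "push_chamber")
  expect_warning(r <- gas_exchange_rates(
    gas_sample(ex$feo2 + 1e-5, ex$feco2, ex$ph2o, 500,
               mode = "push_chamber")), "noise")
  expect_equal(r$vo2, 0)
  expect_false(r$flag)
  # large apparent O2 production: flagged, value kept
  ex2 <- simulate_excurrent(0, 0, 0, 500, mode = "push_chamber")
  expect_warning(r2 <- gas_exchange_rates(
    gas_sample(ex2$feo2 + 5e-4, ex2$feco2, ex2$ph2o, 500,
               mode = "push_chamber")), "flagged")
  expect_true(r2$flag)
  expect_lt(r2$vo2, -0.01)
})

test_that("RER is the CO2/O2 ratio and needs positive VO2", {
  expect_equal(respiratory_exchange_ratio(1.0, 0.85), 0.85)
  expect_equal(respiratory_exchange_ratio(2.0, 2.0), 1.0)
  expect_error(respiratory_exchange_ratio(0.0, 0.5), "positive")
})

test_that("oxyjoule conversion matches hand computations", {
  expect_equal(metabolic_rate(0, 0.8), 0)
  expect_equal(metabolic_rate(1.0, 0.7), (16 + 5.164 * 0.7) / 60)
  # basal-rate magnitude: ~0.68 ml/min at RER 1 gives ~0.24 W
  expect_equal(metabolic_rate(0.68, 1.0), 0.68 * 21.164 / 60)
  expect_error(metabolic_rate(-1, 0.8), "negative")
  expect_warning(metabolic_rate(1, 1.3), "RER")
})

test_that("oxyjoule conversion is linear in VO2 and increasing in RER", {
  vo2 <- c(0.3, 0.9, 1.7)
  expect_equal(metabolic_rate(2 * vo2, 0.85), 2 * metabolic_rate(vo2, 0.85))
  rers <- seq(0.6, 1.1, by = 0.1)
  expect_true(all(diff(metabolic_rate(1, rers)) > 0))
})

test_that("latent-heat conversion is linear with the expected anchors", {
  expect_equal(ehl_from_ewl(0), 0)
  expect_equal(ehl_from_ewl(25), 1.0)
  expect_equal(ehl_from_ewl(1.525), 0.061)
  expect_equal(ehl_from_ewl(c(2, 4)), 2 * ehl_from_ewl(c(1, 2)))
  expect_error(ehl_from_ewl(-1), "negative")
})

test_that("allometric surface area is monotone with As(1) = 10", {
  expect_equal(surface_area(1), 10)
  expect_equal(surface_area(8), 40.03, tolerance = 1e-3)
  expect_equal(surface_area(15), 60.9, tolerance = 1e-3)
  mb <- seq(5, 30, by = 0.5)
  expect_true(all(diff(surface_area(mb)) > 0))
  expect_error(surface_area(0), "positive")
})

test_that("thermal conductance matches hand value and its invariances", {
  expect_equal(thermal_conductance(0.3, 0.3, 41, 23, 15), 0)
  expect_equal(thermal_conductance(0.30, 0.06, 41.0, 23.0, 15),
               2.19e-4, tolerance = 1e-2)
  expect_error(thermal_conductance(0.30, 0.06, 23.0, 41.0, 15), "tb > ta")
  # invariant to a common shift of both temperatures
  for (k in c(-3, 2, 7.5))
    expect_equal(thermal_conductance(0.3, 0.06, 41 + k, 23 + k, 15),
                 thermal_conductance(0.3, 0.06, 41, 23, 15))
  expect_warning(thermal_conductance(0.05, 0.06, 41, 23, 15), "MR below")
})
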