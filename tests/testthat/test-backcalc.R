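test_that("BPH equation is exact at the section edge and at frozen oracle points", {
  # identity at the section edge, no tolerance beyond floating round-off
  expect_identical(back_calculate_length(25.0, 25.0, 60.0), 60.0)
  expect_equal(back_calculate_length(13.7, 13.7, 44.5), 44.5)

  # frozen by independent direct substitution of the equation
  expect_equal(back_calculate_length(20.0, 25.0, 60.0), 48.50908605318958,
               tolerance = 1e-9)
  expect_equal(back_calculate_length(20.0, 25.0, 60.0),
               bph_direct(20, 25, 60), tolerance = 1e-12)

  # closed-form limit at the hatchling diameter: L_op * L_final / denom
  expect_equal(back_calculate_length(2.6, 25.0, 60.0),
               5.1 * 60 / (5.1 + 3.127 * (25 - 2.6)^0.928),
               tolerance = 1e-12)
})

test_that("back-calculation is monotone in D and proportional in L_final", {
  p <- bph_params()
  for (d_final in c(15, 25, 35)) {
    d <- seq(p$d_op, d_final, length.out = 40)
    l <- back_calculate_length(d, d_final, 60, p)
    expect_true(all(diff(l) > 0))
    # BPH scaling: L(D, D_final, a * L_final) = a * L(D, D_final, L_final)
    expect_equal(back_calculate_length(d, d_final, 60 * 1.7, p), 1.7 * l,
                 tolerance = 1e-12)
  }
})

test_that("domain violations raise errors naming the bound", {
  expect_error(back_calculate_length(1.0, 25, 60), "D_op")
  expect_error(back_calculate_length(26.0, 25, 60), "D_final")
  expect_error(back_calculate_length(20, 25, -5), "positive")
  expect_error(bph_params(exponent = 2.5), "exponent")
  expect_error(bph_params(slope = -1), "slope")
})

test_that("inverse round-trips within 1e-9 cm over a grid", {
  p <- bph_params()
  set.seed(42)
  for (rep in 1:50) {
    d_final <- runif(1, 10, 40)
    l_final <- runif(1, 40, 100)
    lo <- back_calculate_length(p$d_op, d_final, l_final, p)
    l <- runif(8, lo, l_final)
    d <- invert_length_to_diameter(l, d_final, l_final, p)
    expect_equal(back_calculate_length(d, d_final, l_final, p), l,
                 tolerance = 1e-9)
  }
  # exact endpoints
  expect_equal(invert_length_to_diameter(60, 25, 60), 25)
  expect_equal(invert_length_to_diameter(48.50908605318958, 25, 60), 20,
               tolerance = 1e-9)
  expect_error(invert_length_to_diameter(3.0, 25, 60), "hatchling")
  expect_error(invert_length_to_diameter(61, 25, 60), "exceeds")
})

test_that("growth history derives annual rates from consecutive years only", {
  rec <- turtle_record("T1", "2000-04-01", 55, "2003-10-01", 62)
  p <- bph_params()
  d_final <- 25
  d <- invert_length_to_diameter(c(55, 58), d_final, 62, p)
  prof <- bone_profile("T1", d, section_diameter = d_final)
  gh <- growth_history(prof, c(2000, 2001), rec, p)
  expect_equal(nrow(gh$rates), 1)
  expect_equal(gh$rates$rate_cm_per_yr, 3.0, tolerance = 1e-9)

  # single LAG: no interval, empty rate list
  prof1 <- bone_profile("T1", d[1], section_diameter = d_final)
  gh1 <- growth_history(prof1, 2000, rec, p)
  expect_equal(nrow(gh1$rates), 0)

  # a gap in years produces no rate across the gap
  d3 <- invert_length_to_diameter(c(55, 58, 60), d_final, 62, p)
  prof3 <- bone_profile("T1", d3, section_diameter = d_final)
  gh3 <- growth_history(prof3, c(2000, 2001, 2003), rec, p)
  expect_equal(gh3$rates$from_year, 2000)

  expect_error(growth_history(prof, c(2000, 2001, 2002), rec, p),
               "misaligned")
})

test_that("noise-free simulated rates equal the simulator's true increments", {
  cfg <- sim_config(n_turtles = 5, scl_error_sd = 0, diameter_error_sd = 0,
                    p_double_lag = 0, stranding_doy_range = c(182, 350),
                    seed = 5)
  sim <- simulate_population(cfg)
  fit <- skelchron(sim$turtles, sim$bones)
  for (id in names(fit$growth)) {
    gh <- fit$growth[[id]]
    tru <- sim$truth[[id]]$lags
    tru <- tru[!tru$resorbed, ]
    truth_rates <- diff(tru$scl_cm)[diff(tru$year) == 1]
    expect_equal(gh$rates$rate_cm_per_yr, truth_rates, tolerance = 1e-6)
  }
})
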