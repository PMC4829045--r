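test_that("double-LAG collapsing keeps the outer line and rejects unpaired flags", {
  # flagged close pair reads as one annual mark with the outer diameter
  expect_equal(collapse_double_lags(c(20.0, 20.1, 22), c(TRUE, TRUE, FALSE)),
               c(20.1, 22))
  # a collapsed double back-calculates to the same SCL as its outer line
  expect_equal(
    back_calculate_length(
      collapse_double_lags(c(20.0, 20.1), c(TRUE, TRUE))[1], 24.6, 60.2),
    back_calculate_length(20.1, 24.6, 60.2))

  # no flags: identity
  d <- c(18, 20, 22)
  expect_identical(collapse_double_lags(d), d)

  # odd flagged run: structural error
  expect_error(collapse_double_lags(c(20, 20.1, 20.2), rep(TRUE, 3)),
               "pairs")
  expect_error(collapse_double_lags(c(20, 21), c(TRUE, FALSE)), "pairs")

  # consecutive annual doubles form an even run of two pairs
  expect_equal(
    collapse_double_lags(c(20, 20.1, 21, 21.1), rep(TRUE, 4)),
    c(20.1, 21.1))

  # never lengthens and preserves strict ordering
  set.seed(1)
  for (rep in 1:20) {
    n <- sample(2:8, 1)
    d <- sort(runif(n, 5, 30))
    fl <- rep(FALSE, n)
    j <- sample(n - 1, 1)
    fl[c(j, j + 1)] <- TRUE
    out <- collapse_double_lags(d, fl)
    expect_lte(length(out), n)
    if (length(out) > 1) expect_true(all(diff(out) > 0))
  }
})

test_that("calendar years honour the spring deposition window at stranding", {
  # spring-stranded, no edge growth: outermost LAG is the stranding year
  a <- assign_lag_years(2, as.Date("2000-05-09"), FALSE)
  expect_equal(a$calendar_year, c(1999, 2000))
  expect_equal(a$basis[2], "edge_same_year")

  # December stranding with edge growth: that spring's LAG already present
  a <- assign_lag_years(3, as.Date("2001-12-11"), TRUE)
  expect_equal(a$calendar_year, c(1999, 2000, 2001))

  # stranded before the nominal deposition date: previous year
  a <- assign_lag_years(1, as.Date("2001-02-01"), FALSE)
  expect_equal(a$calendar_year, 2000)
  expect_equal(a$basis, "edge_previous_year")

  # spring-stranded with measurable edge growth: previous year
  a <- assign_lag_years(2, as.Date("2001-04-23"), TRUE)
  expect_equal(a$calendar_year, c(1999, 2000))

  expect_error(assign_lag_years(0, as.Date("2000-01-01"), FALSE), "empty")

  # years are always consecutive integers ending at the outermost LAG
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(1:15, 1)
    d <- as.Date("1995-01-01") + sample(0:5000, 1)
    a <- assign_lag_years(n, d, sample(c(TRUE, FALSE), 1))
    expect_identical(diff(a$calendar_year), rep(1L, n - 1))
    expect_equal(which.max(a$calendar_year), n)
  }
})

test_that("LAG nearest a target date is selected with a later-LAG tie-break", {
  a <- assign_lag_years(5, as.Date("2002-10-17"), TRUE)  # 1998..2002
  # spring tagging selects the same year's LAG
  sel <- select_lag_nearest_date(a, as.Date("1998-05-12"))
  expect_equal(sel$calendar_year, 1998)
  expect_false(sel$use_otc_fallback)

  # December tagging: the following spring is nearer
  sel <- select_lag_nearest_date(a, as.Date("1998-12-21"))
  expect_equal(sel$calendar_year, 1999)

  # exact midpoint between two nominal deposition dates: later LAG
  mid <- nominal_deposition_date(2000) +
    as.numeric(nominal_deposition_date(2001) - nominal_deposition_date(2000)) / 2
  sel <- select_lag_nearest_date(a, mid)
  expect_equal(sel$calendar_year, 2001)

  # target year below the earliest retained LAG: OTC fallback signal
  sel <- select_lag_nearest_date(a, as.Date("1994-06-17"))
  expect_true(sel$use_otc_fallback)
  expect_equal(sel$ideal_year, 1994)
})

test_that("noise-free simulated bones recover every true deposition year", {
  cfg <- sim_config(n_turtles = 40, scl_error_sd = 0, diameter_error_sd = 0,
                    p_double_lag = 0.15, stranding_doy_range = c(182, 350),
                    seed = 21)
  sim <- simulate_population(cfg)
  fit <- skelchron(sim$turtles, sim$bones)
  for (id in names(fit$growth)) {
    tru <- sim$truth[[id]]$lags
    expect_identical(fit$growth[[id]]$entries$year,
                     tru$year[!tru$resorbed])
  }
})
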