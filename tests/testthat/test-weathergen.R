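test_that("climate_params validates its inputs", {
  expect_error(climate_params(order = 4), "order")
  expect_error(climate_params(p_wet = 1.2), "probabilities")
  expect_error(climate_params(gamma_shape = 0), "gamma")
  expect_error(climate_params(gamma_scale = -1), "gamma")
  expect_error(climate_params(canicula_factor = 1.5), "canicula_factor")
  expect_error(climate_params(persistence = 1), "persistence")
  cp <- climate_params(order = 2, p_wet = matrix(0.4, 12, 4))
  expect_identical(dim(cp$p_wet), c(12L, 4L))
})

test_that("generator is deterministic, non-negative, and degenerate chains behave", {
  cp <- climate_params(order = 2, p_wet = 0.4, gamma_shape = 2, gamma_scale = 4)
  a <- generate_daily(cp, n_years = 3, seed = 7)
  b <- generate_daily(cp, n_years = 3, seed = 7)
  expect_identical(a, b)
  expect_true(all(a$rain_mm >= 0))
  expect_equal(nrow(a), 3L * 365L)

  dry <- climate_params(p_wet = 0)
  expect_true(all(generate_daily(dry, 2, seed = 1)$rain_mm == 0))
})

test_that("always-wet chain reproduces the gamma mean daily rainfall", {
  # wet probability 1, amounts gamma with mean 8 mm
  cp <- climate_params(order = 1, p_wet = 1, gamma_shape = 2, gamma_scale = 4)
  daily <- generate_daily(cp, n_years = 200, seed = 3)
  expect_true(all(daily$rain_mm > 0))
  monthly <- tapply(daily$rain_mm,
                    rep(rainindex:::month_of_doy(1:365), 200), mean)
  expect_true(all(abs(monthly - 8) < 0.3))
  expect_equal(mean(daily$rain_mm), 8, tolerance = 0.01)
})

test_that("wet-day frequency converges to the first-order stationary frequency", {
  p01 <- 0.3; p11 <- 0.7
  cp <- climate_params(order = 1,
                       p_wet = matrix(c(rep(p01, 12), rep(p11, 12)), 12, 2))
  daily <- generate_daily(cp, n_years = 150, seed = 5)
  expect_equal(mean(daily$rain_mm > 0),
               stationary_wet_frequency(p01, p11), tolerance = 0.02)
})

test_that("mid-season dry-spell depression lowers rainfall inside its window", {
  base <- climate_params(order = 1, p_wet = 0.5, gamma_shape = 2,
                         gamma_scale = 4,
                         canicula_factor = 0.5, canicula_window = c(182, 243))
  daily <- generate_daily(base, n_years = 100, seed = 11)
  inside <- daily$rain_mm[daily$doy >= 182 & daily$doy <= 243]
  outside <- daily$rain_mm[daily$doy < 182 | daily$doy > 243]
  expect_lt(mean(inside), mean(outside))
})

test_that("dekad aggregation sums exactly and checks bounds", {
  uniform <- make_daily(rep(1, 90))
  s <- aggregate_to_dekads(uniform, sowing_day = 1, offset_days = 0, n_dekads = 9)
  expect_equal(s$rain_mm, rep(10, 9))
  expect_equal(s$n_dekads, 9L)

  zero <- make_daily(rep(0, 120))
  expect_true(all(aggregate_to_dekads(zero, 30, -10, 8)$rain_mm == 0))

  set.seed(42)
  rnd <- make_daily(round(rexp(365, 1 / 5), 1))
  s2 <- aggregate_to_dekads(rnd, sowing_day = 140, offset_days = -10, n_dekads = 8)
  # brute-force day-by-day oracle
  oracle <- vapply(seq_len(8), function(k) {
    days <- (140 - 10 + (k - 1) * 10):(140 - 10 + k * 10 - 1)
    sum(rnd$rain_mm[rnd$doy %in% days])
  }, 0)
  expect_identical(s2$rain_mm, oracle)
  expect_equal(sum(s2$rain_mm), sum(rnd$rain_mm[rnd$doy >= 130 & rnd$doy <= 209]))

  expect_error(aggregate_to_dekads(make_daily(rep(1, 50)), 40, 0, 8), "outside")
})

test_that("sowing onset rule follows the printed definition", {
  # days 5-9 each 6 mm, k = 5, tau = 5: first qualifying day is 10
  rain <- rep(0, 60); rain[5:9] <- 6
  expect_identical(determine_sowing_date(make_daily(rain), window = c(1, 60)), 10L)

  # only 4 consecutive qualifying days anywhere -> absent
  rain4 <- rep(0, 60); rain4[5:8] <- 6
  expect_identical(determine_sowing_date(make_daily(rain4), window = c(1, 60)),
                   NA_integer_)

  # all days qualify: window start wins because days 15-19 qualify
  expect_identical(determine_sowing_date(make_daily(rep(6, 60)),
                                         window = c(20, 40)), 20L)

  # threshold is strict: exactly tau mm is not a qualifying day
  expect_identical(determine_sowing_date(make_daily(rep(5, 60)),
                                         window = c(10, 40)), NA_integer_)

  expect_error(determine_sowing_date(make_daily(rep(6, 30)), window = c(20, 10)),
               "window")
})

test_that("daily CSV round-trips losslessly", {
  cp <- climate_params(p_wet = 0.4)
  daily <- generate_daily(cp, 2, seed = 9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_daily_csv(daily, path)
  back <- read_daily_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(daily))
})
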