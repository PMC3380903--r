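test_that("deficits ignore surpluses and sum per season", {
  res <- compute_deficit(table4_rain, table3_min)
  expect_equal(res$total_mm, -49.4)
  expect_equal(sum(res$deficit_mm), res$total_mm)
  expect_true(all(res$deficit_mm <= 0))

  none <- compute_deficit(table3_min + 5, table3_min)
  expect_equal(none$total_mm, 0)

  expect_error(compute_deficit(c(1, 2), c(1, 2, 3)), "dekads")
  expect_error(compute_deficit(c(1, 2), c(-1, 2)), "MWR")
})

test_that("raising any MWR entry weakly deepens every total deficit", {
  set.seed(11)
  for (i in 1:10) {
    rain <- runif(8, 0, 70)
    mwr <- runif(8, 0, 50)
    t0 <- compute_deficit(rain, mwr)$total_mm
    d <- sample(8, 1)
    mwr2 <- mwr; mwr2[d] <- mwr2[d] + runif(1, 0, 30)
    expect_lte(compute_deficit(rain, mwr2)$total_mm, t0)
  }
})

test_that("lowest quartile takes floor(n/4) smallest yields with stable ties", {
  rt <- make_run_table(matrix(runif(800), 100), yields = sample(1:100))
  lq <- lowest_quartile(rt)
  expect_equal(nrow(lq), 25L)
  expect_setequal(lq$yield, 1:25)

  rt99 <- make_run_table(matrix(runif(99 * 8), 99), yields = sample(1:99))
  expect_equal(nrow(lowest_quartile(rt99)), 24L)

  tied <- make_run_table(matrix(runif(80), 10), yields = rep(5, 10))
  expect_warning(lqt <- lowest_quartile(tied), "ties")
  expect_identical(lqt$year, 1:2)   # first floor(10/4) rows in input order

  expect_error(lowest_quartile(rt[1:3, ]), "at least 4")
})

test_that("initial heuristic matches its definition and zeroes good years", {
  cfg <- study_config()
  rt <- run_grid("A", default_soils()["deep_loam"], cfg$climate, cfg$crop,
                 n_years = 40, seed = 6)
  mwr0 <- initial_mwr(rt)
  expect_true(all(mwr0 >= 0))

  # independent recomputation: median of top-quartile rain, capped at the
  # minimum over the upper three quartiles
  rain <- dekad_matrix(rt)
  ord <- order(rt$yield)
  m <- floor(nrow(rt) / 4)
  top <- rain[order(-rt$yield)[seq_len(m)], , drop = FALSE]
  rest <- rain[ord[-seq_len(m)], , drop = FALSE]
  oracle <- pmax(pmin(apply(top, 2, median), apply(rest, 2, min)), 0)
  expect_equal(unname(mwr0), unname(oracle))

  # upper and middle yield quartiles carry zero deficit under the start
  for (i in ord[-seq_len(m)]) {
    expect_equal(compute_deficit(rain[i, ], mwr0)$total_mm, 0)
  }

  # all-zero rainfall everywhere -> zero vector
  zero_rt <- make_run_table(matrix(0, 12, 8), yields = runif(12))
  expect_equal(initial_mwr(zero_rt), rep(0, 8))
})

test_that("r_squared equals the textbook squared Pearson correlation", {
  x <- c(-40, -25, -10, 0)
  y <- 100 + 3 * x
  expect_equal(r_squared(x, y), 1)

  # hand-computed 4-point case via the explicit sum formula
  y2 <- c(120, 180, 150, 300)
  n <- 4
  num <- (n * sum(x * y2) - sum(x) * sum(y2))^2
  den <- (n * sum(x^2) - sum(x)^2) * (n * sum(y2^2) - sum(y2)^2)
  expect_equal(r_squared(x, y2), num / den, tolerance = 1e-12)

  set.seed(8)
  expect_lt(r_squared(rnorm(1000), rnorm(1000)), 0.01)

  expect_error(r_squared(rep(1, 5), 1:5), "degenerate")
  expect_error(r_squared(1:2, 1:2), "length")
})

test_that("rainfall index is the plain sum of the MIN row", {
  expect_equal(rainfall_index(table3_min), 195)
  expect_equal(rainfall_index(rep(0, 8)), 0)
  expect_equal(rainfall_index(sample(table3_min)), 195)
})

test_that("optimizer matches exhaustive grid search on 2-dekad toys", {
  set.seed(21)
  for (rep in 1:3) {
    rain <- matrix(runif(2 * 30, 0, 60), 30, 2)
    stress <- pmin(rain[, 1] / 35, 1) * pmin(rain[, 2] / 45, 1)
    yields <- 1500 * stress + rnorm(30, 0, 40)
    rt <- make_run_table(rain, yields)

    grid <- expand.grid(m1 = seq(0, 60, 5), m2 = seq(0, 60, 5))
    grid_obj <- apply(grid, 1, function(m) {
      td <- pmin(rain[, 1] - m[1], 0) + pmin(rain[, 2] - m[2], 0)
      if (sd(td) == 0) 0 else cor(td, yields)^2
    })
    cal <- calibrate_mwr(rt, seed = rep)
    expect_gte(cal$r_squared, max(grid_obj) - 1e-6)
    expect_true(all(cal$mwr >= 0))
  }
})

test_that("optimizer never returns negative entries and never undercuts its start", {
  cfg <- study_config()
  rt <- run_grid("A", default_soils()["shallow_loam"], cfg$climate, cfg$crop,
                 n_years = 40, seed = 3)
  lq <- suppressWarnings(lowest_quartile(rt))
  init <- initial_mwr(lq)
  cal <- calibrate_mwr(lq, init = init, seed = 3)
  expect_true(all(cal$mwr >= 0))
  rain <- dekad_matrix(lq)
  obj_init <- {
    td <- rowSums(pmin(sweep(rain, 2, pmin(init, 80)), 0))
    if (sd(td) == 0) 0 else cor(td, lq$yield)^2
  }
  expect_gte(cal$r_squared, obj_init - 1e-12)
  expect_equal(cal$rainfall_index_mm, sum(cal$mwr))
  expect_length(cal$diagnostics$start_objectives, cal$diagnostics$n_starts)

  flat <- make_run_table(matrix(runif(40), 10), yields = rep(3, 10))
  expect_error(calibrate_mwr(flat), "zero yield variance")
})

test_that("yields driven by a single dekad leave the other MWRs at zero", {
  set.seed(5)
  rain <- matrix(runif(4 * 40, 10, 55), 40, 4)
  yields <- 50 + 20 * rain[, 2]          # affine in dekad 2 only
  rt <- make_run_table(rain, yields)
  cal <- calibrate_mwr(rt, seed = 5)
  expect_gt(cal$r_squared, 0.999)
  expect_true(all(cal$mwr[-2] == 0))
  expect_gt(cal$mwr[2], 0)
})

test_that("calibration recovers known stage demands on noise-free runs", {
  soil0 <- soil_profile("sand", "shallow", whc_mm = 5, runoff_frac = 0)
  crop0 <- crop_params(demand_mm = c(10, 20, 30, 45, 60, 50, 35, 15),
                       sensitivity = rep(0.6, 8), noise_sd = 0,
                       init_storage_frac = 0, trickle_mm = 0)
  rt <- run_grid("A", list(s = soil0), milder_climate(), crop0,
                 n_years = 99, seed = 42)
  lq <- suppressWarnings(lowest_quartile(rt))
  cal <- calibrate_mwr(lq, seed = 42)
  expect_gte(cal$r_squared, 0.9)
  expect_gte(cor(cal$mwr, crop0$demand_mm, method = "spearman"), 0.8)
})

test_that("calibration results serialize to JSON and back", {
  rt <- make_run_table(matrix(runif(80, 0, 60), 10), yields = runif(10, 100, 900))
  cal <- calibrate_mwr(rt, seed = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration_json(cal, path)
  back <- read_calibration_json(path)
  expect_equal(back$mwr, cal$mwr)
  expect_equal(back$r_squared, cal$r_squared)
  expect_equal(back$rainfall_index_mm, cal$rainfall_index_mm)
})
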