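test_that("soil library honours texture, depth and slope orderings", {
  soils <- default_soils()
  expect_length(soils, 8L)
  for (t in c("sand", "loam", "clay_loam", "silty_clay")) {
    expect_lt(soils[[paste0("shallow_", t)]]$whc_mm,
              soils[[paste0("deep_", t)]]$whc_mm)
  }
  # runoff grows with texture heaviness and with slope
  ro <- vapply(c("sand", "loam", "clay_loam", "silty_clay"),
               runoff_fraction, 0)
  expect_true(all(diff(ro) > 0))
  expect_gt(runoff_fraction("loam", slope = 0.3), runoff_fraction("loam", 0))
  expect_lte(runoff_fraction("silty_clay", slope = 5), 0.9)

  expect_error(soil_profile("sand", whc_mm = 0), "WHC")
  expect_error(soil_profile("sand", runoff_frac = 1), "runoff")
})

test_that("water balance conserves the bucket and caps storage at WHC", {
  soil <- default_soils()$deep_loam
  crop <- crop_params(noise_sd = 0)
  set.seed(1)
  for (i in 1:20) {
    rain <- round(runif(8, 0, 150), 1)
    wb <- water_balance(rain, soil, crop)
    expect_equal(wb$infiltration_mm, rain * (1 - soil$runoff_frac))
    expect_true(all(wb$storage_mm >= 0 & wb$storage_mm <= soil$whc_mm))
    expect_true(all(wb$supply_mm <= wb$available_mm + 1e-12))
    expect_true(all(wb$relative_supply >= 0 & wb$relative_supply <= 1))
    # opening + inputs = uptake + closing + drainage (drainage >= 0)
    open <- c(crop$init_storage_frac * soil$whc_mm, wb$storage_mm[-8])
    drainage <- open + wb$infiltration_mm + crop$trickle_mm -
      wb$supply_mm - wb$storage_mm
    expect_true(all(drainage >= -1e-12))
  }
})

test_that("yield responds to water as the stress model requires", {
  soil_free <- soil_profile("loam", "deep", runoff_frac = 0)
  crop <- crop_params(noise_sd = 0)

  # no rain at all: near-total crop failure
  dry <- dekadal_season(rep(0, 8))
  expect_lt(simulate_yield(dry, default_soils()$deep_loam, crop),
            0.05 * crop$potential_kg_ha)

  # demand met exactly in every dekad (340 mm total): potential yield
  met <- dekadal_season(crop$demand_mm)
  expect_equal(simulate_yield(met, soil_free, crop), crop$potential_kg_ha)

  # bounded by [0, potential] and deterministic per seed, noise on
  noisy <- crop_params()
  set.seed(3)
  for (i in 1:10) {
    season <- dekadal_season(runif(8, 0, 80))
    y1 <- simulate_yield(season, soil_free, noisy, seed = i)
    y2 <- simulate_yield(season, soil_free, noisy, seed = i)
    expect_identical(y1, y2)
    expect_gte(y1, 0)
    expect_lte(y1, noisy$potential_kg_ha)
  }
})

test_that("adding rainfall to any dekad never lowers noise-free yield", {
  soil <- default_soils()$shallow_sand
  crop <- crop_params(noise_sd = 0)
  set.seed(7)
  for (i in 1:15) {
    rain <- runif(8, 0, 60)
    y0 <- simulate_yield(dekadal_season(rain), soil, crop)
    d <- sample(8, 1)
    rain2 <- rain; rain2[d] <- rain2[d] + runif(1, 1, 40)
    expect_gte(simulate_yield(dekadal_season(rain2), soil, crop), y0 - 1e-12)
  }
})

test_that("droughtier soils yield less on identical marginal seasons", {
  sand <- default_soils()$shallow_sand
  clay <- default_soils()$deep_silty_clay
  crop <- crop_params(noise_sd = 0)
  daily <- generate_daily(study_config()$climate, n_years = 60, seed = 13)
  ys <- yc <- numeric(60)
  for (y in 1:60) {
    season <- aggregate_to_dekads(daily, 150, -10, 8, year = y)
    ys[y] <- simulate_yield(season, sand, crop)
    yc[y] <- simulate_yield(season, clay, crop)
  }
  expect_lt(mean(ys), mean(yc))
  # and expected yield rises with WHC at fixed texture/runoff
  small <- soil_profile("loam", "shallow", runoff_frac = 0.05, whc_mm = 40)
  big <- soil_profile("loam", "deep", runoff_frac = 0.05, whc_mm = 120)
  ys2 <- vapply(1:60, function(y) {
    season <- aggregate_to_dekads(daily, 150, -10, 8, year = y)
    simulate_yield(season, small, crop) - simulate_yield(season, big, crop)
  }, 0)
  expect_lte(mean(ys2), 0)
})

test_that("run_grid accounts for every pixel, soil and year", {
  cfg <- study_config()
  rt <- run_grid(c("A", "B"), default_soils()[c("deep_loam", "shallow_sand")],
                 cfg$climate, cfg$crop, n_years = 6, seed = 2)
  expect_s3_class(rt, "run_table")
  expect_equal(nrow(rt), 2 * 2 * 6)
  expect_true(all(rt$yield >= 0))
  expect_equal(nrow(unique(rt[, c("pixel", "soil", "year")])), nrow(rt))

  single <- run_grid("A", default_soils()["deep_loam"], cfg$climate, cfg$crop,
                     n_years = 1, seed = 2)
  expect_equal(nrow(single), 1L)

  # reproducibility
  rt2 <- run_grid(c("A", "B"), default_soils()[c("deep_loam", "shallow_sand")],
                  cfg$climate, cfg$crop, n_years = 6, seed = 2)
  expect_identical(rt, rt2)

  expect_error(run_grid(character(0), default_soils(), cfg$climate, cfg$crop,
                        5, 1), "at least one")
})

test_that("run_plan enumerates the simulation grid without running it", {
  plan <- run_plan(c("A", "B", "C"), default_soils(), 99)
  expect_equal(nrow(plan), 3 * 8 * 99)
  expect_identical(names(plan), c("pixel", "soil", "year"))
})

test_that("run table CSV round-trips", {
  cfg <- study_config()
  rt <- run_grid("A", default_soils()["deep_loam"], cfg$climate, cfg$crop,
                 n_years = 5, seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_run_table(rt, path)
  expect_equal(as.data.frame(read_run_table(path)), as.data.frame(rt))
})
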