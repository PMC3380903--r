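# Shared fixtures: built in code, no stored data.

# Droughty study climate: the conditions shipped in the demo config.
study_config <- function() {
  read_pipeline_config(system.file("extdata", "demo_config.yml",
                                   package = "rainindex"))
}

# Milder matched-grid climate for cross-soil comparisons: the regime where
# drought stress is moderate rather than catastrophic.
milder_climate <- function() {
  climate_params(
    order = 3,
    p_wet = c(.05, .05, .05, .10, .52, .65, .65, .65, .65, .585, .15, .05),
    gamma_shape = 2.5, gamma_scale = 4,
    persistence = 0.2, canicula_factor = 0.8
  )
}

# Minimal run-table data.frame from a rain matrix and a yield vector.
make_run_table <- function(rain, yields, pixel = "PX", soil = "S1") {
  rain <- as.matrix(rain)
  colnames(rain) <- paste0("dekad_", seq_len(ncol(rain)))
  df <- data.frame(pixel = pixel, soil = soil, year = seq_len(nrow(rain)),
                   rain, yield = yields, stringsAsFactors = FALSE)
  class(df) <- c("run_table", "data.frame")
  df
}

# One year of daily data from a plain rain vector (doy 1..length).
make_daily <- function(rain_mm, year = 1L) {
  d <- data.frame(year = year, doy = seq_along(rain_mm), rain_mm = rain_mm)
  class(d) <- c("daily_series", "data.frame")
  d
}

table3_min <- c(0, 10, 10, 25, 40, 40, 40, 30, 0)
table4_rain <- c(34.9, 22.4, 0.6, 33.8, 0, 57.6, 73.4, 161.8, 112.9)
table5_rain <- c(5.8, 3.6, 0, 9.5, 4.1, 23.5, 12.6, 2, 96.1)

sample_contract <- function(trigger_mm = -70) {
  contract_spec(
    station = "San Dionisio reference station",
    crop = "Dry beans - drought tolerant type",
    soil = "Deep sand",
    mwr = table3_min, trigger_mm = trigger_mm,
    indemnity_rate = 5, premium = 3
  )
}
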