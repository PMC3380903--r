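# End-to-end pipeline: generate weather -> simulate yields -> calibrate
# MWRs -> write contracts -> price. Driven by a declarative YAML config;
# every artifact records the master seed.

#' Read a pipeline configuration
#'
#' Loads a YAML pipeline config and validates it: master seed, pixel list
#' (ids, optional lat/lon), climate parameters (shared or per pixel), soil
#' set (subset of the eight generic soils, or custom), crop parameters,
#' calibration window, contract template (trigger, indemnity rate, premium,
#' sowing rule) and pricing triggers/loading.
#'
#' @param path Path to the YAML config file.
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  build_pipeline_config(raw)
}

#' Build a pipeline configuration from a list
#'
#' Programmatic equivalent of [read_pipeline_config()]; see that function
#' for the fields.
#'
#' @param x Named list with elements `seed`, `n_years`, `pixels`, `climate`,
#'   `soils`, `crop`, `window`, `contract`, `pricing`.
#' @return A `pipeline_config` list.
#' @export
build_pipeline_config <- function(x) {
  req <- c("seed", "n_years", "pixels")
  miss <- setdiff(req, names(x))
  if (length(miss) > 0L) {
    stop("config missing required fields: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  pixels <- if (is.data.frame(x$pixels)) x$pixels else {
    do.call(rbind, lapply(x$pixels, function(p) {
      data.frame(pixel = p$id,
                 lat = if (is.null(p$lat)) NA_real_ else p$lat,
                 lon = if (is.null(p$lon)) NA_real_ else p$lon,
                 stringsAsFactors = FALSE)
    }))
  }

  cl <- x$climate
  climate <- if (is.null(cl)) climate_params() else {
    climate_params(order = if (is.null(cl$order)) 3L else cl$order,
                   p_wet = if (is.null(cl$p_wet)) 0.35 else unlist(cl$p_wet),
                   gamma_shape = if (is.null(cl$gamma_shape)) 1.5 else unlist(cl$gamma_shape),
                   gamma_scale = if (is.null(cl$gamma_scale)) 6 else unlist(cl$gamma_scale),
                   persistence = if (is.null(cl$persistence)) 0 else cl$persistence,
                   canicula_factor = cl$canicula_factor,
                   canicula_window = if (is.null(cl$canicula_window)) c(182L, 243L)
                                     else unlist(cl$canicula_window))
  }

  all_soils <- default_soils(slope = if (is.null(x$slope)) 0 else x$slope)
  soils <- if (is.null(x$soils)) all_soils else {
    unknown <- setdiff(unlist(x$soils), names(all_soils))
    if (length(unknown) > 0L) {
      stop("unknown soils in config (soil library has: ",
           paste(names(all_soils), collapse = ", "), "): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    all_soils[unlist(x$soils)]
  }

  cr <- x$crop
  crop <- if (is.null(cr)) crop_params() else {
    do.call(crop_params, cr[intersect(names(cr),
      c("demand_mm", "sensitivity", "potential_kg_ha", "noise_sd",
        "init_storage_frac"))])
  }

  w <- x$window
  window <- list(offset_days = if (is.null(w$offset_days)) -10L else as.integer(w$offset_days),
                 n_dekads = if (is.null(w$n_dekads)) 8L else as.integer(w$n_dekads),
                 sowing_window = if (is.null(w$sowing_window)) c(135L, 166L)
                                 else as.integer(unlist(w$sowing_window)),
                 sowing_rule = if (is.null(w$sowing_rule)) list(k = 5L, tau = 5)
                               else list(k = as.integer(w$sowing_rule$k),
                                         tau = as.numeric(w$sowing_rule$tau)))

  ct <- x$contract
  contract <- list(
    station = if (is.null(ct$station)) "reference station" else ct$station,
    crop_name = if (is.null(ct$crop)) "dry beans" else ct$crop,
    trigger_mm = if (is.null(ct$trigger_mm)) -70 else as.numeric(ct$trigger_mm),
    indemnity_rate = if (is.null(ct$indemnity_rate)) 5 else as.numeric(ct$indemnity_rate),
    premium = if (is.null(ct$premium)) NA_real_ else as.numeric(ct$premium),
    currency = if (is.null(ct$currency)) "USD" else ct$currency
  )

  pr <- x$pricing
  pricing <- list(
    triggers_mm = if (is.null(pr$triggers_mm)) c(-50, -70) else as.numeric(unlist(pr$triggers_mm)),
    loading = if (is.null(pr$loading)) 0 else as.numeric(pr$loading)
  )

  structure(
    list(seed = as.integer(x$seed), n_years = as.integer(x$n_years),
         pixels = pixels, climate = climate, soils = soils, crop = crop,
         window = window, contract = contract, pricing = pricing),
    class = "pipeline_config"
  )
}

#' Run the full index-design pipeline
#'
#' generate weather -> simulate the run table -> calibrate an MWR row per
#' (pixel, soil) on the lowest yield quartile -> write a contract per cell
#' -> price every cell at the configured triggers. Artifacts written to
#' `out_dir`: `run_table.csv`, `calibration/<pixel>_<soil>.json`,
#' `contracts/<pixel>_<soil>.yml`, `risk_grid.csv`, `pipeline_log.txt`.
#' Deterministic for a fixed config (same seed = byte-identical numbers).
#'
#' @param config A `pipeline_config`.
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the in-memory artifacts: `run_table`,
#'   `calibrations` (named list), `contracts` (named list), `risk`
#'   (risk_summary), `paths`.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "calibration"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "contracts"), showWarnings = FALSE)
  log_lines <- c(
    sprintf("rainindex pipeline  seed=%d", config$seed),
    sprintf("pixels=%d soils=%d years=%d window=%d dekads from day %+d",
            nrow(config$pixels), length(config$soils), config$n_years,
            config$window$n_dekads, config$window$offset_days)
  )
  say <- function(msg) if (!quiet) message(msg)

  say("simulating run table ...")
  rt <- run_grid(pixels = config$pixels$pixel, soils = config$soils,
                 climate = config$climate, crop = config$crop,
                 n_years = config$n_years, seed = config$seed,
                 sowing_window = config$window$sowing_window,
                 sowing_rule = config$window$sowing_rule,
                 offset_days = config$window$offset_days,
                 n_dekads = config$window$n_dekads)
  rt_path <- file.path(out_dir, "run_table.csv")
  write_run_table(rt, rt_path)
  log_lines <- c(log_lines, sprintf("run_table rows=%d", nrow(rt)))

  calibrations <- list()
  contracts <- list()
  for (px in config$pixels$pixel) {
    for (so in names(config$soils)) {
      cell <- paste(px, so, sep = "_")
      sub <- rt[rt$pixel == px & rt$soil == so, , drop = FALSE]
      lq <- withCallingHandlers(
        lowest_quartile(sub),
        warning = function(w) invokeRestart("muffleWarning")
      )
      cal <- tryCatch(
        calibrate_mwr(lq, seed = config$seed),
        error = function(e) stop(sprintf("calibration failed for pixel %s soil %s: %s",
                                         px, so, conditionMessage(e)), call. = FALSE)
      )
      calibrations[[cell]] <- cal
      write_calibration_json(cal, file.path(out_dir, "calibration",
                                            paste0(cell, ".json")))
      spec <- contract_spec(
        station = config$contract$station, crop = config$contract$crop_name,
        soil = so, mwr = round(cal$mwr, 1),
        trigger_mm = config$contract$trigger_mm,
        indemnity_rate = config$contract$indemnity_rate,
        premium = config$contract$premium,
        sowing_window = config$window$sowing_window,
        sowing_rule = config$window$sowing_rule,
        currency = config$contract$currency
      )
      contracts[[cell]] <- spec
      write_contract(spec, file.path(out_dir, "contracts", paste0(cell, ".yml")))
      log_lines <- c(log_lines,
                     sprintf("calibrated %s: index=%.1f mm R2=%.3f", cell,
                             cal$rainfall_index_mm, cal$r_squared))
    }
  }
  say(sprintf("calibrated %d cells", length(calibrations)))

  template <- contracts[[1L]]
  risk <- risk_map(rt, template, triggers_mm = config$pricing$triggers_mm,
                   loading = config$pricing$loading,
                   calibrations = calibrations)
  risk_path <- file.path(out_dir, "risk_grid.csv")
  write_risk_grid(risk, risk_path, coords = config$pixels)
  log_lines <- c(log_lines, sprintf("risk rows=%d", nrow(risk)))

  writeLines(log_lines, file.path(out_dir, "pipeline_log.txt"))
  say("done")
  invisible(list(run_table = rt, calibrations = calibrations,
                 contracts = contracts, risk = risk,
                 paths = list(run_table = rt_path, risk_grid = risk_path,
                              out_dir = out_dir)))
}

#' Write a dekadal-season CSV (`year, dekad_index, rain_mm`)
#'
#' @param seasons Either one [dekadal_season()] or a named list (names =
#'   years).
#' @param path File path.
#' @return `read_dekadal_csv` returns a data.frame; `write_dekadal_csv`
#'   returns `path` invisibly.
#' @export
write_dekadal_csv <- function(seasons, path) {
  if (inherits(seasons, "dekadal_season")) seasons <- list(`1` = seasons)
  rows <- do.call(rbind, lapply(names(seasons), function(y) {
    s <- seasons[[y]]
    data.frame(year = as.integer(y), dekad_index = seq_len(s$n_dekads),
               rain_mm = s$rain_mm)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dekadal_csv
#' @export
read_dekadal_csv <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("year", "dekad_index", "rain_mm") %in% names(d)))
  d
}
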