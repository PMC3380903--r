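# Soil-bucket water-balance yield model: a seeded stand-in for a full
# process crop model. Yield responds to per-dekad water supply relative to
# stage demand, with stage-specific sensitivity, so that yield loss has the
# dekadal-deficit structure a rainfall index presumes.

#' Soil profile
#'
#' Texture class, profile depth class, plant-available water-holding
#' capacity (WHC) and a runoff fraction. Runoff increases with texture
#' heaviness (finer texture = lower infiltration rate) and with slope;
#' available storage is larger on deep profiles and coarse-through-fine
#' textures hold more plant-available water than sands.
#'
#' @param texture One of `"sand"`, `"loam"`, `"clay_loam"`, `"silty_clay"`
#'   (ordered light to heavy).
#' @param depth `"deep"` or `"shallow"`.
#' @param slope Fractional slope (0 = flat; 0.3 = 30 percent), feeding the
#'   runoff fraction.
#' @param whc_mm Plant-available water-holding capacity in mm; default from
#'   the built-in texture x depth lookup.
#' @param runoff_frac Fraction of rainfall lost to runoff, in `[0, 1)`;
#'   default [runoff_fraction()] of texture and slope.
#' @return A `soil_profile` object.
#' @examples
#' soil_profile("sand", "shallow")
#' soil_profile("silty_clay", "deep", slope = 0.3)
#' @export
soil_profile <- function(texture = c("sand", "loam", "clay_loam", "silty_clay"),
                         depth = c("deep", "shallow"),
                         slope = 0,
                         whc_mm = NULL,
                         runoff_frac = NULL) {
  texture <- match.arg(texture)
  depth <- match.arg(depth)
  if (!is.finite(slope) || slope < 0) stop("`slope` must be >= 0", call. = FALSE)
  if (is.null(whc_mm)) whc_mm <- .whc_lookup[[depth]][[texture]]
  if (!is.finite(whc_mm) || whc_mm <= 0) stop("WHC must be > 0", call. = FALSE)
  if (is.null(runoff_frac)) runoff_frac <- runoff_fraction(texture, slope)
  if (!is.finite(runoff_frac) || runoff_frac < 0 || runoff_frac >= 1) {
    stop("runoff fraction must be in [0, 1)", call. = FALSE)
  }
  structure(list(texture = texture, depth = depth, slope = slope,
                 whc_mm = whc_mm, runoff_frac = runoff_frac,
                 id = paste(depth, texture, sep = "_")),
            class = "soil_profile")
}

# Plant-available WHC (mm) defaults: texture x depth.
.whc_lookup <- list(
  deep    = list(sand = 60,  loam = 110, clay_loam = 130, silty_clay = 140),
  shallow = list(sand = 30,  loam = 55,  clay_loam = 65,  silty_clay = 70)
)

# Base runoff fraction by texture (heavier = more runoff).
.runoff_base <- c(sand = 0.02, loam = 0.06, clay_loam = 0.10, silty_clay = 0.15)

#' Runoff fraction from texture and slope
#'
#' Fraction of rainfall lost to surface runoff: a texture base rate plus a
#' slope term, `base + 0.5 * slope`, capped at 0.9. Heavier textures and
#' steeper slopes shed more water.
#'
#' @param texture Texture class (see [soil_profile()]).
#' @param slope Fractional slope.
#' @return Runoff fraction in `[0, 0.9]`.
#' @export
runoff_fraction <- function(texture, slope = 0) {
  base <- .runoff_base[[texture]]
  min(base + 0.5 * slope, 0.9)
}

#' @export
print.soil_profile <- function(x, ...) {
  cat(sprintf("<soil_profile> %s %s: WHC %.0f mm, runoff %.0f%%, slope %.0f%%\n",
              x$depth, x$texture, x$whc_mm, 100 * x$runoff_frac, 100 * x$slope))
  invisible(x)
}

#' The eight generic soils
#'
#' Four texture classes (sand, loam, clay loam, silty clay) crossed with
#' deep and shallow profiles, with default WHC and runoff fractions.
#'
#' @param slope Fractional slope applied to all eight (default 0).
#' @return A named list of eight `soil_profile` objects.
#' @export
default_soils <- function(slope = 0) {
  tex <- c("sand", "loam", "clay_loam", "silty_clay")
  out <- list()
  for (d in c("deep", "shallow")) for (t in tex) {
    s <- soil_profile(t, d, slope = slope)
    out[[s$id]] <- s
  }
  out
}

#' Crop parameters for the water-limited yield model
#'
#' @param demand_mm Per-dekad crop water demand (mm/dekad), one entry per
#'   dekad of the season window; the default (length 8, day -10 to +70)
#'   totals 340 mm, inside the 300-400 mm optimum band for a 60-75 day
#'   drybean cycle.
#' @param sensitivity Per-dekad stress-sensitivity exponents (>= 0), peaking
#'   mid-cycle (flowering / pod fill).
#' @param potential_kg_ha Water-unlimited yield (kg/ha).
#' @param noise_sd Standard deviation of the multiplicative lognormal yield
#'   noise on the log scale; 0 disables noise (deterministic mode).
#' @param init_storage_frac Soil water at window start, as a fraction of WHC.
#' @param trickle_mm Residual water supply per dekad (mm) available to the
#'   crop regardless of rainfall — capillary rise, dew and moisture below
#'   the nominal root zone. Keeps the relative supply strictly positive, so
#'   drought stress degrades yield gradually instead of an abrupt total
#'   failure the moment one dekad's store runs dry.
#' @return A `crop_params` object.
#' @export
crop_params <- function(demand_mm = c(10, 25, 40, 55, 60, 55, 55, 40),
                        sensitivity = c(0.2, 0.4, 0.6, 1.0, 1.2, 1.2, 0.8, 0.4),
                        potential_kg_ha = 2500,
                        noise_sd = 0.05,
                        init_storage_frac = 0.4,
                        trickle_mm = 2) {
  demand_mm <- as.numeric(demand_mm)
  sensitivity <- as.numeric(sensitivity)
  if (length(demand_mm) != length(sensitivity)) {
    stop("`demand_mm` and `sensitivity` must have one entry per dekad",
         call. = FALSE)
  }
  if (any(!is.finite(demand_mm)) || any(demand_mm < 0)) {
    stop("demands must be finite and >= 0", call. = FALSE)
  }
  if (any(!is.finite(sensitivity)) || any(sensitivity < 0)) {
    stop("sensitivities must be finite and >= 0", call. = FALSE)
  }
  if (!is.finite(potential_kg_ha) || potential_kg_ha <= 0) {
    stop("potential yield must be > 0", call. = FALSE)
  }
  if (!is.finite(noise_sd) || noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (!is.finite(init_storage_frac) || init_storage_frac < 0 || init_storage_frac > 1) {
    stop("init_storage_frac must be in [0, 1]", call. = FALSE)
  }
  if (!is.finite(trickle_mm) || trickle_mm < 0) {
    stop("trickle_mm must be >= 0", call. = FALSE)
  }
  structure(list(demand_mm = demand_mm, sensitivity = sensitivity,
                 n_dekads = length(demand_mm),
                 potential_kg_ha = potential_kg_ha,
                 noise_sd = noise_sd,
                 init_storage_frac = init_storage_frac,
                 trickle_mm = trickle_mm),
            class = "crop_params")
}

#' @export
print.crop_params <- function(x, ...) {
  cat(sprintf("<crop_params> %d dekads, total demand %.0f mm, potential %.0f kg/ha\n",
              x$n_dekads, sum(x$demand_mm), x$potential_kg_ha))
  invisible(x)
}

#' Simulate water-limited yield for one season
#'
#' Runs a per-dekad bucket water balance: infiltration is rainfall times
#' `(1 - runoff_frac)`; available water is carried storage plus
#' infiltration; crop uptake is `min(available, demand)`; the remainder is
#' stored up to WHC (excess drains). Yield is the multiplicative
#' stage-stress form
#' `potential * prod_d (min(1, supply_d / demand_d)) ^ sensitivity_d`,
#' optionally times mean-one lognormal noise, capped at the potential.
#'
#' @param season A [dekadal_season()] covering the crop cycle.
#' @param soil A [soil_profile()].
#' @param crop A [crop_params()] with the same dekad count as `season`.
#' @param seed Integer seed for the yield noise (ignored when
#'   `noise_sd = 0`).
#' @return Yield in kg/ha (single number in `[0, potential]`).
#' @export
simulate_yield <- function(season, soil, crop, seed = 1L) {
  stopifnot(inherits(season, "dekadal_season"),
            inherits(soil, "soil_profile"),
            inherits(crop, "crop_params"))
  if (season$n_dekads < crop$n_dekads) {
    stop(sprintf("season has %d dekads but the crop cycle needs %d",
                 season$n_dekads, crop$n_dekads), call. = FALSE)
  }
  stress <- water_stress_index(season$rain_mm[seq_len(crop$n_dekads)], soil, crop)
  y <- crop$potential_kg_ha * stress
  if (crop$noise_sd > 0) {
    set.seed(as.integer(seed))
    # mean-one lognormal
    y <- y * stats::rlnorm(1L, meanlog = -crop$noise_sd^2 / 2, sdlog = crop$noise_sd)
  }
  min(max(y, 0), crop$potential_kg_ha)
}

#' Trace the dekadal soil water balance
#'
#' Runs the bucket water balance of [simulate_yield()] and returns the full
#' trace: per dekad the rainfall, infiltration (`rain * (1 - runoff_frac)`),
#' water available to the crop (carried storage + infiltration + trickle),
#' crop uptake (`min(available, demand)`), the relative supply
#' `min(1, supply / demand)` and the closing storage (capped at WHC, never
#' negative; excess drains).
#'
#' @param season A [dekadal_season()] or numeric per-dekad rain vector.
#' @param soil A [soil_profile()].
#' @param crop A [crop_params()].
#' @return A data.frame with one row per dekad: `dekad`, `rain_mm`,
#'   `infiltration_mm`, `available_mm`, `supply_mm`, `relative_supply`,
#'   `storage_mm`.
#' @export
water_balance <- function(season, soil, crop) {
  rain_mm <- if (inherits(season, "dekadal_season")) season$rain_mm else as.numeric(season)
  rain_mm <- rain_mm[seq_len(crop$n_dekads)]
  storage <- crop$init_storage_frac * soil$whc_mm
  out <- data.frame(dekad = seq_along(rain_mm), rain_mm = rain_mm,
                    infiltration_mm = 0, available_mm = 0, supply_mm = 0,
                    relative_supply = 0, storage_mm = 0)
  for (d in seq_along(rain_mm)) {
    infil <- rain_mm[d] * (1 - soil$runoff_frac)
    avail <- storage + infil + crop$trickle_mm
    demand <- crop$demand_mm[d]
    supply <- min(avail, demand)
    rel <- if (demand > 0) supply / demand else 1
    storage <- min(avail - supply, soil$whc_mm)
    out[d, 3:7] <- c(infil, avail, supply, rel, storage)
  }
  out
}

# Deterministic stress multiplier in [0, 1] from the dekadal water balance.
water_stress_index <- function(rain_mm, soil, crop) {
  wb <- water_balance(rain_mm, soil, crop)
  prod(wb$relative_supply^crop$sensitivity)
}

#' Index table of a simulation grid
#'
#' The (pixel, soil, year) index over which [run_grid()] simulates: one row
#' per combination, without running anything. Useful for accounting, e.g.
#' 151 pixels x 8 soils x 99 years = 119,592 runs.
#'
#' @param pixels Character vector of pixel ids.
#' @param soils List of `soil_profile`s (or character ids).
#' @param n_years Years per pixel.
#' @return A data.frame with columns `pixel`, `soil`, `year`.
#' @export
run_plan <- function(pixels, soils, n_years) {
  soil_ids <- vapply(soils, function(s) if (is.character(s)) s else s$id, "")
  plan <- expand.grid(year = seq_len(n_years), soil = soil_ids, pixel = pixels,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  plan[, c("pixel", "soil", "year")]
}

#' Simulate a grid of pixels, soils and years
#'
#' For each pixel: generates daily weather from its climate parameters,
#' determines the sowing date for each year (onset rule, falling back to the
#' end of the sowing window when the rule is never met), aggregates rainfall
#' to dekads, and simulates the yield on every soil. One row per
#' (pixel, soil, year) — a "run table", the calibration substrate.
#'
#' @param pixels Character vector of pixel ids.
#' @param soils List of [soil_profile()]s.
#' @param climate A single [climate_params()] shared by all pixels, or a
#'   named list with one entry per pixel.
#' @param crop A [crop_params()].
#' @param n_years Years to simulate per pixel.
#' @param seed Master seed (weather and yield noise both derive from it).
#' @param sowing_window Integer `c(first_doy, last_doy)` for the onset rule
#'   (default 15 May to 15 June, days 135-166).
#' @param sowing_rule List with elements `k` and `tau` for
#'   [determine_sowing_date()].
#' @param offset_days,n_dekads Dekad window relative to sowing (default
#'   day -10 to +70 = 8 dekads).
#' @return A `run_table` data.frame: `pixel`, `soil`, `year`,
#'   `dekad_1..dekad_N`, `yield`.
#' @export
run_grid <- function(pixels, soils, climate, crop, n_years, seed,
                     sowing_window = c(135L, 166L),
                     sowing_rule = list(k = 5L, tau = 5),
                     offset_days = -10L, n_dekads = 8L) {
  if (length(pixels) < 1L || length(soils) < 1L) {
    stop("need at least one pixel and one soil", call. = FALSE)
  }
  if (inherits(climate, "climate_params")) {
    climate <- stats::setNames(rep(list(climate), length(pixels)), pixels)
  }
  if (!all(pixels %in% names(climate))) {
    stop("`climate` must be a climate_params or a named list covering every pixel",
         call. = FALSE)
  }
  if (crop$n_dekads > n_dekads) {
    stop("crop cycle longer than the dekad window", call. = FALSE)
  }
  soil_ids <- vapply(soils, function(s) s$id, "")

  rows <- vector("list", length(pixels))
  for (i in seq_along(pixels)) {
    px <- pixels[i]
    px_seed <- as.integer((as.integer(seed) + 7919L * i) %% 2147483647L)
    daily <- generate_daily(climate[[px]], n_years, seed = px_seed)
    block <- vector("list", n_years)
    for (y in seq_len(n_years)) {
      dy <- daily[daily$year == y, , drop = FALSE]
      sow <- determine_sowing_date(dy, window = sowing_window,
                                   k = sowing_rule$k, tau = sowing_rule$tau)
      if (is.na(sow)) sow <- sowing_window[2L]
      season <- aggregate_to_dekads(dy, sowing_day = sow,
                                    offset_days = offset_days,
                                    n_dekads = n_dekads)
      yields <- vapply(seq_along(soils), function(j) {
        simulate_yield(season, soils[[j]], crop,
                       seed = px_seed + 131L * y + 17L * j)
      }, 0)
      rmat <- matrix(season$rain_mm, nrow = length(soils),
                     ncol = n_dekads, byrow = TRUE)
      colnames(rmat) <- paste0("dekad_", seq_len(n_dekads))
      block[[y]] <- data.frame(pixel = px, soil = soil_ids, year = y,
                               rmat, yield = yields,
                               stringsAsFactors = FALSE, row.names = NULL)
    }
    rows[[i]] <- do.call(rbind, block)
  }
  rt <- do.call(rbind, rows)
  rt <- rt[order(match(rt$pixel, pixels), match(rt$soil, soil_ids), rt$year), ]
  rownames(rt) <- NULL
  class(rt) <- c("run_table", "data.frame")
  rt
}

#' Extract the dekadal rainfall matrix of a run table
#'
#' @param runs A `run_table` (or any data.frame with `dekad_*` columns).
#' @return Numeric matrix, one row per run, one column per dekad.
#' @export
dekad_matrix <- function(runs) {
  cols <- grep("^dekad_[0-9]+$", names(runs), value = TRUE)
  cols <- cols[order(as.integer(sub("^dekad_", "", cols)))]
  as.matrix(runs[, cols, drop = FALSE])
}

#' Read / write a run table CSV
#'
#' @param runs A `run_table` data.frame.
#' @param path File path.
#' @return `read_run_table` returns a `run_table`; `write_run_table` returns
#'   `path` invisibly.
#' @export
write_run_table <- function(runs, path) {
  utils::write.csv(as.data.frame(runs), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_run_table
#' @export
read_run_table <- function(path) {
  rt <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("pixel", "soil", "year", "yield") %in% names(rt)))
  class(rt) <- c("run_table", "data.frame")
  rt
}
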