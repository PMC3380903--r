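# Actuarial summaries: empirical trigger-exceedance probabilities and
# burn-rate premiums per pixel and soil. Probabilities are empirical counts;
# no distribution is fitted and no tail extrapolation is attempted.

#' Empirical trigger-exceedance probability
#'
#' Fraction of seasons whose total rainfall deficit reaches (is at or below)
#' the trigger.
#'
#' @param totals Numeric vector of total deficits (mm, <= 0), one per season.
#' @param trigger_mm Trigger value (mm, negative).
#' @return Probability in `[0, 1]`.
#' @export
exceedance_probability <- function(totals, trigger_mm) {
  totals <- as.numeric(totals)
  if (length(totals) < 1L) stop("`totals` is empty", call. = FALSE)
  mean(totals <= trigger_mm)
}

#' Price a contract on a run-table subset
#'
#' Evaluates every simulated season of one pixel x soil against the
#' contract, then summarizes: exceedance probability at the contract's
#' trigger, expected payout per season, the actuarially fair premium
#' (= expected payout) and a loaded premium `fair * (1 + loading)`.
#'
#' @param spec A [contract_spec()].
#' @param runs A `run_table` subset sharing the contract's pixel/soil
#'   (>= 1 row), with `dekad_*` columns matching the MIN row length.
#' @param loading Premium loading factor `lambda >= 0` (default 0).
#' @return A `risk_summary` data.frame row: `pixel`, `soil`, `trigger_mm`,
#'   `prob`, `expected_payout`, `fair_premium`, `loaded_premium`.
#' @export
price_contract <- function(spec, runs, loading = 0) {
  stopifnot(inherits(spec, "contract_spec"))
  if (is.null(nrow(runs)) || nrow(runs) < 1L) {
    stop("`runs` is empty", call. = FALSE)
  }
  if (!is.finite(loading) || loading < 0) {
    stop("`loading` must be >= 0", call. = FALSE)
  }
  rain <- dekad_matrix(runs)
  if (ncol(rain) != length(spec$mwr)) {
    stop("run table dekad count does not match the contract MIN row", call. = FALSE)
  }
  totals <- total_deficits(rain, spec$mwr)
  payouts <- spec$indemnity_rate *
    pmax(0, abs(totals) - abs(spec$trigger_mm)) * (totals <= spec$trigger_mm)
  expected <- mean(payouts)
  out <- data.frame(
    pixel = if ("pixel" %in% names(runs)) runs$pixel[1L] else NA_character_,
    soil = if ("soil" %in% names(runs)) runs$soil[1L] else NA_character_,
    trigger_mm = spec$trigger_mm,
    prob = exceedance_probability(totals, spec$trigger_mm),
    expected_payout = expected,
    fair_premium = expected,
    loaded_premium = expected * (1 + loading),
    stringsAsFactors = FALSE
  )
  class(out) <- c("risk_summary", "data.frame")
  out
}

#' Risk map over a full run table
#'
#' For every (pixel, soil, trigger) computes the exceedance probability and
#' premiums, and appends a soil-averaged summary per (pixel, trigger)
#' (soil = `"mean"`, arithmetic mean over soils of probabilities and
#' payouts). Missing (pixel, soil) cells raise an error rather than being
#' silently skipped.
#'
#' @param run_table Full `run_table` across pixels and soils.
#' @param spec_template A [contract_spec()] whose indemnity rate, currency
#'   and (absent per-cell calibrations) MIN row are used for every cell; its
#'   trigger is replaced by each value of `triggers_mm`.
#' @param triggers_mm Numeric vector of (negative) triggers, e.g.
#'   `c(-50, -70)`.
#' @param loading Premium loading factor.
#' @param calibrations Optional named list of per-cell MWR rows (names
#'   `"<pixel>_<soil>"`, values either numeric vectors or
#'   `calibration_result`s): each cell's deficits are then computed against
#'   its own calibrated MIN row, as when every soil within every pixel
#'   carries its own index.
#' @return A `risk_summary` data.frame, per-soil rows then soil means.
#' @export
risk_map <- function(run_table, spec_template, triggers_mm = c(-50, -70),
                     loading = 0, calibrations = NULL) {
  stopifnot(inherits(spec_template, "contract_spec"))
  pixels <- unique(run_table$pixel)
  soils <- unique(run_table$soil)
  missing_cells <- character(0)
  rows <- list()
  for (px in pixels) {
    for (so in soils) {
      sub <- run_table[run_table$pixel == px & run_table$soil == so, , drop = FALSE]
      if (nrow(sub) == 0L) {
        missing_cells <- c(missing_cells, paste(px, so, sep = "/"))
        next
      }
      cell <- paste(px, so, sep = "_")
      mwr <- spec_template$mwr
      if (!is.null(calibrations) && !is.null(calibrations[[cell]])) {
        cc <- calibrations[[cell]]
        mwr <- if (inherits(cc, "calibration_result")) cc$mwr else as.numeric(cc)
      }
      for (tr in triggers_mm) {
        spec <- spec_template
        spec$mwr <- validate_mwr(mwr)
        spec$trigger_mm <- tr
        rows[[length(rows) + 1L]] <- price_contract(spec, sub, loading)
      }
    }
  }
  if (length(missing_cells) > 0L) {
    stop("missing (pixel, soil) cells in run table: ",
         paste(missing_cells, collapse = ", "), call. = FALSE)
  }
  per_soil <- do.call(rbind, rows)
  means <- do.call(rbind, lapply(split(
    per_soil, list(per_soil$pixel, per_soil$trigger_mm), drop = TRUE
  ), function(g) {
    data.frame(pixel = g$pixel[1L], soil = "mean", trigger_mm = g$trigger_mm[1L],
               prob = mean(g$prob),
               expected_payout = mean(g$expected_payout),
               fair_premium = mean(g$fair_premium),
               loaded_premium = mean(g$loaded_premium),
               stringsAsFactors = FALSE)
  }))
  out <- rbind(per_soil, means)
  rownames(out) <- NULL
  out <- out[order(match(out$pixel, pixels), out$soil != "mean",
                   match(out$soil, c(soils, "mean")), -out$trigger_mm), ]
  rownames(out) <- NULL
  class(out) <- c("risk_summary", "data.frame")
  out
}

#' Write a risk grid CSV
#'
#' @param risk A `risk_summary` data.frame (from [risk_map()]).
#' @param path File path.
#' @param coords Optional data.frame `pixel, lat, lon` merged in.
#' @return `path`, invisibly.
#' @export
write_risk_grid <- function(risk, path, coords = NULL) {
  out <- as.data.frame(risk)
  if (!is.null(coords)) {
    out <- merge(coords, out, by = "pixel", sort = FALSE)
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
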