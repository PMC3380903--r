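# Stochastic daily rainfall: Markov-chain occurrence + gamma amounts.
# Stand-in for a full tropical weather generator; first- to third-order
# occurrence chains because a first-order chain cannot reproduce the
# persistence of tropical wet and dry spells.

DAYS_PER_YEAR <- 365L

#' Climate parameters for the daily rainfall generator
#'
#' Defines a seasonal Markov-chain / gamma rainfall process. Rain occurrence
#' follows a wet/dry Markov chain whose state is the wet/dry history of the
#' last `order` days (order 1-3, default 3: higher-order persistence is
#' needed to reproduce tropical wet- and dry-spell lengths). Wet-day amounts
#' are gamma distributed. All parameters are monthly (12 columns/entries),
#' so a bimodal wet season with a mid-season dry spell can be encoded either
#' directly in the monthly values or via the `canicula_*` arguments, which
#' multiply the wet-day probability inside a fixed calendar window by a
#' depression factor.
#'
#' @param order Occurrence-chain order, integer in 1..3. The chain has
#'   `2^order` states; state `s` is the binary encoding of the last `order`
#'   wet/dry indicators (most recent day = least significant bit).
#' @param p_wet Wet-day probability given history. Either a single number
#'   (used for all months and states), a length-12 vector (per month, all
#'   states equal), or a `12 x 2^order` matrix (month x history state).
#' @param gamma_shape,gamma_scale Gamma parameters of wet-day rainfall (mm);
#'   scalar or length-12 (per month). Mean wet-day rain = shape * scale.
#' @param persistence Spell persistence in `[0, 1)`, applied when `p_wet` is
#'   given as a scalar or per-month vector: the wet probability in history
#'   state with `w` wet days out of `order` is scaled by
#'   `1 + persistence * (2 * w / order - 1)` (clamped to `[0, 1]`), so runs
#'   of wet days raise and runs of dry days lower the chance of rain —
#'   the clustered wet/dry spells typical of tropical rainfall. Ignored when
#'   `p_wet` is a full month x state matrix.
#' @param canicula_factor Optional multiplier in `[0, 1]` applied to the
#'   wet probability inside the mid-season dry-spell window; `NULL` disables.
#' @param canicula_window Integer vector `c(first_doy, last_doy)` of the
#'   dry-spell window (default days 182-243, July-August).
#'
#' @return An object of class `climate_params`.
#' @examples
#' cp <- climate_params(order = 1, p_wet = 0.4, gamma_shape = 2, gamma_scale = 4)
#' daily <- generate_daily(cp, n_years = 2, seed = 1)
#' @export
climate_params <- function(order = 3L,
                           p_wet = 0.35,
                           gamma_shape = 1.5,
                           gamma_scale = 6,
                           persistence = 0,
                           canicula_factor = NULL,
                           canicula_window = c(182L, 243L)) {
  order <- as.integer(order)
  if (length(order) != 1L || is.na(order) || !(order %in% 1:3)) {
    stop("`order` must be 1, 2 or 3", call. = FALSE)
  }
  n_states <- 2L^order

  if (length(persistence) != 1L || !is.finite(persistence) ||
      persistence < 0 || persistence >= 1) {
    stop("`persistence` must be a single number in [0, 1)", call. = FALSE)
  }
  scalar_p <- !is.matrix(p_wet)
  p_wet <- expand_monthly(p_wet, n_states, "p_wet")
  if (scalar_p && persistence > 0) {
    # state s has popcount(s) wet days in the last `order`
    wet_count <- vapply(0:(n_states - 1L), function(s) {
      sum(bitwAnd(s, 2L^(0:(order - 1L))) > 0L)
    }, 0L)
    mult <- 1 + persistence * (2 * wet_count / order - 1)
    p_wet <- pmin(pmax(sweep(p_wet, 2L, mult, `*`), 0), 1)
  }
  if (any(!is.finite(p_wet)) || any(p_wet < 0) || any(p_wet > 1)) {
    stop("`p_wet` entries must be probabilities in [0, 1]", call. = FALSE)
  }
  gamma_shape <- expand_monthly(gamma_shape, 1L, "gamma_shape")[, 1L]
  gamma_scale <- expand_monthly(gamma_scale, 1L, "gamma_scale")[, 1L]
  if (any(!is.finite(gamma_shape)) || any(gamma_shape <= 0) ||
      any(!is.finite(gamma_scale)) || any(gamma_scale <= 0)) {
    stop("gamma shape and scale must be finite and > 0", call. = FALSE)
  }
  if (!is.null(canicula_factor)) {
    if (length(canicula_factor) != 1L || !is.finite(canicula_factor) ||
        canicula_factor < 0 || canicula_factor > 1) {
      stop("`canicula_factor` must be a single number in [0, 1]", call. = FALSE)
    }
    canicula_window <- as.integer(canicula_window)
    if (length(canicula_window) != 2L || any(is.na(canicula_window)) ||
        canicula_window[1L] < 1L || canicula_window[2L] > DAYS_PER_YEAR ||
        canicula_window[1L] > canicula_window[2L]) {
      stop("`canicula_window` must be c(first_doy, last_doy) within 1..365",
           call. = FALSE)
    }
  }
  structure(
    list(order = order, p_wet = p_wet,
         gamma_shape = gamma_shape, gamma_scale = gamma_scale,
         canicula_factor = canicula_factor,
         canicula_window = if (is.null(canicula_factor)) NULL else canicula_window),
    class = "climate_params"
  )
}

# Recycle scalar / length-12 / 12 x k input into a 12 x k matrix.
expand_monthly <- function(x, k, name) {
  if (is.matrix(x)) {
    if (nrow(x) != 12L || ncol(x) != k) {
      stop(sprintf("`%s` matrix must be 12 x %d (month x state)", name, k),
           call. = FALSE)
    }
    return(x)
  }
  if (length(x) == 1L) return(matrix(x, 12L, k))
  if (length(x) == 12L) return(matrix(x, 12L, k))
  stop(sprintf("`%s` must be a scalar, length-12 vector or 12 x %d matrix",
               name, k), call. = FALSE)
}

#' @export
print.climate_params <- function(x, ...) {
  cat(sprintf("<climate_params> order-%d occurrence chain, monthly gamma amounts\n",
              x$order))
  cat(sprintf("  mean wet-day prob %.3f; mean wet-day rain %.1f mm\n",
              mean(x$p_wet), mean(x$gamma_shape * x$gamma_scale)))
  if (!is.null(x$canicula_factor)) {
    cat(sprintf("  mid-season dry spell: factor %.2f on days %d-%d\n",
                x$canicula_factor, x$canicula_window[1L], x$canicula_window[2L]))
  }
  invisible(x)
}

# Month (1-12) of each day-of-year in a 365-day year.
month_of_doy <- function(doy) {
  ends <- cumsum(c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L))
  findInterval(doy - 1L, c(0L, ends[-12L]) )
}

#' Generate multi-year daily rainfall
#'
#' Simulates `n_years` years of daily rainfall (365-day years, leap days
#' ignored) from a `climate_params` process. The random stream for each year
#' is derived deterministically from the master seed, so the series is
#' reproducible and individual years are independent of how many years are
#' requested.
#'
#' @param params A [climate_params()] object.
#' @param n_years Number of years to generate (>= 1).
#' @param seed Master integer seed.
#' @return A `daily_series` data.frame with columns `year` (1-based index),
#'   `doy` (day-of-year, 1..365) and `rain_mm` (>= 0).
#' @export
generate_daily <- function(params, n_years, seed) {
  if (!inherits(params, "climate_params")) {
    stop("`params` must be a climate_params object", call. = FALSE)
  }
  n_years <- as.integer(n_years)
  if (is.na(n_years) || n_years < 1L) stop("`n_years` must be >= 1", call. = FALSE)
  seed <- as.integer(seed)

  order <- params$order
  month <- month_of_doy(seq_len(DAYS_PER_YEAR))
  p_wet <- params$p_wet
  depress <- rep(1, DAYS_PER_YEAR)
  if (!is.null(params$canicula_factor)) {
    w <- params$canicula_window
    depress[w[1L]:w[2L]] <- params$canicula_factor
  }

  out <- vector("list", n_years)
  state <- 0L                      # dry history carried across year boundary
  mask <- 2L^order - 1L
  for (y in seq_len(n_years)) {
    # per-year substream: deterministic function of master seed and year
    set.seed((seed %% 599999L) * 3571L + y)
    u <- stats::runif(DAYS_PER_YEAR)
    rain <- numeric(DAYS_PER_YEAR)
    for (d in seq_len(DAYS_PER_YEAR)) {
      p <- p_wet[month[d], state + 1L] * depress[d]
      wet <- u[d] < p
      if (wet) {
        rain[d] <- stats::rgamma(1L, shape = params$gamma_shape[month[d]],
                                 scale = params$gamma_scale[month[d]])
      }
      state <- bitwAnd(bitwShiftL(state, 1L) + as.integer(wet), mask)
    }
    out[[y]] <- data.frame(year = y, doy = seq_len(DAYS_PER_YEAR), rain_mm = rain)
  }
  res <- do.call(rbind, out)
  class(res) <- c("daily_series", "data.frame")
  res
}

#' Aggregate daily rainfall to dekads around a sowing date
#'
#' Sums daily rainfall of one year into consecutive half-open 10-day blocks
#' (dekads) covering the window
#' `[sowing_day + offset_days, sowing_day + offset_days + 10 * n_dekads)`.
#' The canonical calibration window, day -10 to day +70 relative to sowing,
#' is `offset_days = -10, n_dekads = 8`; a 90-day contract sheet counted from
#' day 1 is `offset_days = 0, n_dekads = 9`.
#'
#' @param daily A `daily_series` data.frame (single year, or pass `year` to
#'   select one).
#' @param sowing_day Sowing day-of-year.
#' @param offset_days Start of the window relative to sowing (e.g. -10).
#' @param n_dekads Number of dekads.
#' @param year Which year of `daily` to use (default the only/first year).
#' @return A `dekadal_season` list with fields `sowing_day`, `offset_days`,
#'   `n_dekads` and `rain_mm` (per-dekad totals).
#' @export
aggregate_to_dekads <- function(daily, sowing_day, offset_days = -10L,
                                n_dekads = 8L, year = NULL) {
  stopifnot(is.data.frame(daily), all(c("doy", "rain_mm") %in% names(daily)))
  if (!is.null(year)) daily <- daily[daily$year == year, , drop = FALSE]
  if ("year" %in% names(daily) && length(unique(daily$year)) > 1L) {
    stop("`daily` spans several years; pass `year` to select one", call. = FALSE)
  }
  sowing_day <- as.integer(sowing_day)
  offset_days <- as.integer(offset_days)
  n_dekads <- as.integer(n_dekads)
  start <- sowing_day + offset_days
  end <- start + 10L * n_dekads - 1L
  if (start < min(daily$doy) || end > max(daily$doy)) {
    stop(sprintf("dekad window [%d, %d] outside available days [%d, %d]",
                 start, end, min(daily$doy), max(daily$doy)), call. = FALSE)
  }
  rain <- daily$rain_mm[match(start:end, daily$doy)]
  totals <- as.numeric(tapply(rain, rep(seq_len(n_dekads), each = 10L), sum))
  dekadal_season(totals, sowing_day = sowing_day, offset_days = offset_days)
}

#' Construct a dekadal season
#'
#' @param rain_mm Per-dekad rainfall totals (mm, >= 0).
#' @param sowing_day Sowing day-of-year (NA if not applicable).
#' @param offset_days Window offset relative to sowing.
#' @return A `dekadal_season` object.
#' @export
dekadal_season <- function(rain_mm, sowing_day = NA_integer_, offset_days = -10L) {
  rain_mm <- as.numeric(rain_mm)
  if (length(rain_mm) < 1L || any(!is.finite(rain_mm)) || any(rain_mm < 0)) {
    stop("dekad totals must be finite and >= 0", call. = FALSE)
  }
  structure(list(sowing_day = as.integer(sowing_day),
                 offset_days = as.integer(offset_days),
                 n_dekads = length(rain_mm),
                 rain_mm = rain_mm),
            class = "dekadal_season")
}

#' @export
print.dekadal_season <- function(x, ...) {
  cat(sprintf("<dekadal_season> %d dekads from day %+d of sowing day %s\n",
              x$n_dekads, x$offset_days,
              if (is.na(x$sowing_day)) "?" else x$sowing_day))
  cat("  rain (mm):", paste(format(x$rain_mm, trim = TRUE), collapse = " "), "\n")
  invisible(x)
}

#' Determine the sowing date from a rainfall onset rule
#'
#' Applies a rule of the form "first day after `k` consecutive rainy days
#' over `tau` mm each": returns the first day `d` inside the sowing window
#' such that days `d-k .. d-1` each received strictly more than `tau` mm.
#'
#' @param daily A `daily_series` data.frame (one year; pass `year` otherwise).
#' @param window Integer `c(first_doy, last_doy)` sowing window, e.g.
#'   `c(135, 166)` for 15 May to 15 June.
#' @param k Required run of qualifying days (default 5).
#' @param tau Per-day rainfall threshold in mm, exceeded strictly (default 5).
#' @param year Which year of `daily` to use.
#' @return The sowing day-of-year, or `NA_integer_` if the rule is never met
#'   inside the window.
#' @export
determine_sowing_date <- function(daily, window, k = 5L, tau = 5, year = NULL) {
  stopifnot(is.data.frame(daily), all(c("doy", "rain_mm") %in% names(daily)))
  if (!is.null(year)) daily <- daily[daily$year == year, , drop = FALSE]
  window <- as.integer(window)
  if (length(window) != 2L || any(is.na(window)) || window[1L] > window[2L]) {
    stop("`window` must be c(first_doy, last_doy) with first <= last",
         call. = FALSE)
  }
  k <- as.integer(k)
  wet <- daily$rain_mm > tau      # "rainy day over tau mm" = strictly greater
  doy <- daily$doy
  for (d in window[1L]:window[2L]) {
    prev <- match((d - k):(d - 1L), doy)
    if (anyNA(prev)) next
    if (all(wet[prev])) return(d)
  }
  NA_integer_
}

#' Stationary wet-day frequency of a first-order occurrence chain
#'
#' For `order = 1` parameters with wet probabilities `p01` (wet | dry) and
#' `p11` (wet | wet), the long-run wet-day frequency is
#' `p01 / (1 + p01 - p11)`. Used as the convergence reference for the
#' generator.
#'
#' @param p01 P(wet | yesterday dry).
#' @param p11 P(wet | yesterday wet).
#' @return Stationary probability of a wet day.
#' @export
stationary_wet_frequency <- function(p01, p11) {
  p01 / (1 + p01 - p11)
}

#' Read / write daily rainfall CSV
#'
#' Lossless CSV round-trip of a daily series (`year, doy, rain_mm`).
#' @param daily A `daily_series` data.frame.
#' @param path File path.
#' @return `read_daily_csv` returns a `daily_series`; `write_daily_csv`
#'   returns `path` invisibly.
#' @export
write_daily_csv <- function(daily, path) {
  utils::write.csv(as.data.frame(daily)[, c("year", "doy", "rain_mm")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_daily_csv
#' @export
read_daily_csv <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("year", "doy", "rain_mm") %in% names(d)))
  class(d) <- c("daily_series", "data.frame")
  d
}
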