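# Rainfall insurance contract: the MIN/RAIN/DEF sheet, sowing rule,
# trigger test and indemnity computation.

#' Construct an insurance contract specification
#'
#' Captures every field of a rainfall-deficit contract sheet: the reference
#' weather station whose official record settles claims, the crop and
#' reference soil the MIN row was calibrated for, the sowing window and
#' onset rule, the MIN row itself (per-dekad minimum water requirements),
#' the trigger on the total seasonal deficit, the premium, and the per-mm
#' indemnity rate paid on deficit in excess of the trigger.
#'
#' @param station Reference weather station id/name.
#' @param crop Crop description.
#' @param soil Reference soil type description.
#' @param sowing_window Character like `"15 May to 15 June"` (documentary)
#'   or integer `c(first_doy, last_doy)`.
#' @param sowing_rule List with `k` (consecutive rainy days) and `tau`
#'   (per-day mm threshold, exceeded strictly).
#' @param mwr Numeric MIN row (mm, >= 0), one entry per dekad.
#' @param trigger_mm Trigger on the total deficit (mm, negative, e.g. -70).
#' @param premium Premium price (currency units).
#' @param indemnity_rate Payment per mm of deficit beyond the trigger
#'   (currency/mm, >= 0).
#' @param currency Currency tag (default `"USD"`).
#' @return A `contract_spec` object.
#' @examples
#' spec <- contract_spec(
#'   station = "San Dionisio", crop = "Dry beans", soil = "Deep sand",
#'   mwr = c(0, 10, 10, 25, 40, 40, 40, 30, 0),
#'   trigger_mm = -70, premium = 3, indemnity_rate = 5
#' )
#' evaluate_season(spec, c(5.8, 3.6, 0, 9.5, 4.1, 23.5, 12.6, 2, 96.1))
#' @export
contract_spec <- function(station, crop, soil,
                          mwr, trigger_mm, indemnity_rate,
                          premium = NA_real_,
                          sowing_window = c(135L, 166L),
                          sowing_rule = list(k = 5L, tau = 5),
                          currency = "USD") {
  mwr <- validate_mwr(mwr)
  if (!is.finite(trigger_mm) || trigger_mm >= 0) {
    stop("`trigger_mm` must be negative (a deficit threshold)", call. = FALSE)
  }
  if (!is.finite(indemnity_rate) || indemnity_rate < 0) {
    stop("`indemnity_rate` must be >= 0", call. = FALSE)
  }
  structure(
    list(station = station, crop = crop, soil = soil,
         sowing_window = sowing_window, sowing_rule = sowing_rule,
         mwr = mwr, trigger_mm = as.numeric(trigger_mm),
         premium = as.numeric(premium),
         indemnity_rate = as.numeric(indemnity_rate),
         currency = currency),
    class = "contract_spec"
  )
}

#' Evaluate one season against a contract
#'
#' Fills in the RAIN and DEF rows: per-dekad deficit `min(rain - MIN, 0)`,
#' total deficit, the trigger flag (total at or below the trigger), and the
#' indemnity payout `rate * max(0, |total| - |trigger|)`. A season exactly
#' at the trigger is flagged as triggered but the excess — and hence the
#' payout — is zero.
#'
#' @param spec A [contract_spec()].
#' @param season A [dekadal_season()] or numeric per-dekad rain vector with
#'   the same dekad count as the MIN row.
#' @return A `season_evaluation` list: `rain_mm`, `deficit_mm`, `total_mm`,
#'   `triggered`, `payout`, `currency`.
#' @export
evaluate_season <- function(spec, season) {
  stopifnot(inherits(spec, "contract_spec"))
  rain <- if (inherits(season, "dekadal_season")) season$rain_mm else as.numeric(season)
  def <- compute_deficit(rain, spec$mwr)
  triggered <- def$total_mm <= spec$trigger_mm
  payout <- if (triggered) {
    spec$indemnity_rate * max(0, abs(def$total_mm) - abs(spec$trigger_mm))
  } else 0
  structure(
    list(rain_mm = rain, deficit_mm = def$deficit_mm, total_mm = def$total_mm,
         triggered = triggered, payout = payout, currency = spec$currency),
    class = "season_evaluation"
  )
}

#' @export
print.season_evaluation <- function(x, ...) {
  cat(sprintf("<season_evaluation> total deficit %.1f mm; %s; payout %s %.2f\n",
              x$total_mm,
              if (x$triggered) "TRIGGERED" else "not triggered",
              x$currency, x$payout))
  invisible(x)
}

#' Render a contract (and optionally an evaluated season) as a text sheet
#'
#' Reproduces the familiar contract-sheet layout: header fields, then the
#' MIN / RAIN / DEF rows by dekad and the total rainfall deficit. With no
#' evaluation the RAIN and DEF rows are left blank for the policyholder to
#' fill in.
#'
#' @param spec A [contract_spec()].
#' @param eval Optional [evaluate_season()] result.
#' @return A character vector of lines (invisibly printed with `cat`-style
#'   `writeLines` by the caller); returned, not printed.
#' @export
render_contract <- function(spec, eval = NULL) {
  n <- length(spec$mwr)
  fmt_cell <- function(x) {
    ifelse(is.na(x), "", sub("\\.0$", "", sprintf("%.1f", x)))
  }
  sow_win <- if (is.numeric(spec$sowing_window)) {
    sprintf("day %d to day %d", spec$sowing_window[1L], spec$sowing_window[2L])
  } else as.character(spec$sowing_window)
  lines <- c(
    "RAINFALL INSURANCE CONTRACT",
    sprintf("Reference weather station : %s", spec$station),
    sprintf("Crop                      : %s", spec$crop),
    sprintf("Reference soil type       : %s", spec$soil),
    sprintf("Sowing window             : %s", sow_win),
    sprintf("Sowing date rule          : first day after %d consecutive rainy days over %s mm each",
            spec$sowing_rule$k, format(spec$sowing_rule$tau)),
    sprintf("Trigger value             : %s mm", format(spec$trigger_mm)),
    sprintf("Premium price             : %s %s", spec$currency,
            if (is.na(spec$premium)) "-" else format(spec$premium)),
    sprintf("Indemnity                 : %s %s for every mm of rainfall deficit after the trigger value",
            spec$currency, format(spec$indemnity_rate)),
    ""
  )
  hdr <- c("", sprintf("D%d", seq_len(n)))
  min_row <- c("MIN", fmt_cell(spec$mwr))
  if (is.null(eval)) {
    rain_row <- c("RAIN", rep("", n))
    def_row <- c("DEF", rep("", n))
    total_line <- "TOTAL rainfall deficit    :"
  } else {
    rain_row <- c("RAIN", fmt_cell(eval$rain_mm))
    def_row <- c("DEF", ifelse(eval$deficit_mm < 0, fmt_cell(eval$deficit_mm), ""))
    total_line <- sprintf("TOTAL rainfall deficit    : %s mm%s",
                          fmt_cell(eval$total_mm),
                          if (eval$triggered) {
                            sprintf("  => indemnity %s %.2f", eval$currency, eval$payout)
                          } else "  => no indemnity")
  }
  w <- max(nchar(c(hdr, min_row, rain_row, def_row)))
  pad <- function(row) paste(formatC(row, width = w), collapse = " ")
  c(lines, pad(hdr), pad(min_row), pad(rain_row), pad(def_row), "", total_line)
}

#' Write / read a contract file (YAML)
#'
#' One contract per file; the write -> read -> write cycle is byte-stable.
#'
#' @param spec A [contract_spec()].
#' @param path File path.
#' @return `read_contract` returns a `contract_spec`; `write_contract`
#'   returns `path` invisibly.
#' @export
write_contract <- function(spec, path) {
  x <- unclass(spec)
  x$sowing_window <- as.integer(x$sowing_window)
  writeLines(yaml::as.yaml(x, precision = 12L), path)
  invisible(path)
}

#' @rdname write_contract
#' @export
read_contract <- function(path) {
  x <- yaml::read_yaml(path)
  contract_spec(station = x$station, crop = x$crop, soil = x$soil,
                sowing_window = as.integer(x$sowing_window),
                sowing_rule = list(k = as.integer(x$sowing_rule$k),
                                   tau = as.numeric(x$sowing_rule$tau)),
                mwr = as.numeric(x$mwr), trigger_mm = x$trigger_mm,
                premium = if (is.null(x$premium)) NA_real_ else as.numeric(x$premium),
                indemnity_rate = x$indemnity_rate, currency = x$currency)
}

#' @export
print.contract_spec <- function(x, ...) {
  writeLines(render_contract(x))
  invisible(x)
}
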