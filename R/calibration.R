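# MWR calibration: find per-dekad minimum water requirements (mm) such that
# the total rainfall deficit of the lowest yield quartile maximally
# correlates with yield. The MWR row is the insurance index; the rainfall
# index of a run is the sum of its MWRs.

#' Per-dekad rainfall deficit against an MWR row
#'
#' For each dekad, the deficit is `min(rain - mwr, 0)`: shortfalls below the
#' minimum water requirement count, surpluses are ignored. The total deficit
#' for the season is the sum of the per-dekad deficits (always <= 0).
#'
#' @param season A [dekadal_season()] (or bare numeric rain vector).
#' @param mwr Numeric MWR vector (mm, >= 0), same length as the season.
#' @return A list with `deficit_mm` (per-dekad, <= 0) and `total_mm`.
#' @examples
#' mwr <- c(0, 10, 10, 25, 40, 40, 40, 30, 0)
#' rain <- c(34.9, 22.4, 0.6, 33.8, 0, 57.6, 73.4, 161.8, 112.9)
#' compute_deficit(rain, mwr)$total_mm   # -49.4
#' @export
compute_deficit <- function(season, mwr) {
  rain <- if (inherits(season, "dekadal_season")) season$rain_mm else as.numeric(season)
  mwr <- validate_mwr(mwr)
  if (length(rain) != length(mwr)) {
    stop(sprintf("season has %d dekads but MWR has %d entries",
                 length(rain), length(mwr)), call. = FALSE)
  }
  d <- pmin(rain - mwr, 0)
  list(deficit_mm = d, total_mm = sum(d))
}

validate_mwr <- function(mwr) {
  mwr <- as.numeric(mwr)
  if (length(mwr) < 1L || any(!is.finite(mwr)) || any(mwr < 0)) {
    stop("MWR entries must be finite and >= 0", call. = FALSE)
  }
  mwr
}

# Total deficits for every row of a rain matrix (rows = runs).
total_deficits <- function(rain_matrix, mwr) {
  d <- sweep(rain_matrix, 2L, mwr)
  rowSums(pmin(d, 0))
}

#' Rainfall index of an MWR row
#'
#' The sum of the per-dekad minimum water requirements (mm): the seasonal
#' rainfall below which the index registers deficit.
#'
#' @param mwr Numeric MWR vector.
#' @return Total in mm.
#' @export
rainfall_index <- function(mwr) {
  sum(validate_mwr(mwr))
}

#' Lowest yield quartile of a run table
#'
#' Returns the `floor(n/4)` rows with the smallest yields. Ties are broken
#' by stable input order (a warning is issued when ties straddle the
#' quartile boundary, e.g. all yields equal).
#'
#' @param runs A `run_table` subset (one pixel x soil), >= 4 rows.
#' @return The subset of `runs` in the lowest quartile.
#' @export
lowest_quartile <- function(runs) {
  n <- nrow(runs)
  if (is.null(n) || n < 4L) {
    stop("need at least 4 runs to take a lowest quartile", call. = FALSE)
  }
  m <- floor(n / 4)
  ord <- order(runs$yield)                  # stable: ties keep input order
  cutoff <- runs$yield[ord[m]]
  if (sum(runs$yield == cutoff) > 1L && any(runs$yield[ord[-seq_len(m)]] == cutoff)) {
    warning("yield ties at the quartile boundary broken by input order")
  }
  runs[sort(ord[seq_len(m)]), , drop = FALSE]
}

# Highest-yield floor(n/4) rows (for the initial heuristic).
top_quartile <- function(runs) {
  n <- nrow(runs)
  m <- floor(n / 4)
  ord <- order(-runs$yield)
  runs[sort(ord[seq_len(m)]), , drop = FALSE]
}

#' Plausible starting MWR row
#'
#' A heuristic start for the optimizer: the per-dekad median rainfall of the
#' top-quartile-yield runs, capped at the per-dekad minimum rainfall over
#' the upper and middle yield quartiles. The cap guarantees that runs with
#' good yields carry a total deficit of exactly zero under the starting MWR
#' — only the drought-struck quartile registers shortfall.
#'
#' @param runs A `run_table` subset (one pixel x soil).
#' @return Numeric MWR vector (mm, >= 0), one entry per dekad.
#' @export
initial_mwr <- function(runs) {
  if (is.null(nrow(runs)) || nrow(runs) < 1L) {
    stop("`runs` is empty", call. = FALSE)
  }
  rain <- dekad_matrix(runs)
  if (nrow(runs) < 4L) {
    return(unname(pmax(apply(rain, 2L, stats::median), 0)))
  }
  med_top <- apply(dekad_matrix(top_quartile(runs)), 2L, stats::median)
  n <- nrow(runs)
  m <- floor(n / 4)
  ord <- order(runs$yield)
  upper_mid <- rain[sort(ord[-seq_len(m)]), , drop = FALSE]
  unname(pmax(pmin(med_top, apply(upper_mid, 2L, min)), 0))
}

#' Squared Pearson correlation
#'
#' @param totals Total-deficit values, one per run.
#' @param yields Yields, same length (>= 3).
#' @return R-squared in `[0, 1]`.
#' @export
r_squared <- function(totals, yields) {
  totals <- as.numeric(totals); yields <- as.numeric(yields)
  if (length(totals) != length(yields) || length(totals) < 3L) {
    stop("`totals` and `yields` must have equal length >= 3", call. = FALSE)
  }
  if (stats::sd(totals) == 0 || stats::sd(yields) == 0) {
    stop("degenerate input: zero variance", call. = FALSE)
  }
  stats::cor(totals, yields)^2
}

# Objective for the optimizer: R^2 of total deficit vs yield, 0 when the
# deficits are constant (no shortfall anywhere = nothing to correlate).
deficit_objective <- function(mwr, rain_matrix, yields) {
  td <- total_deficits(rain_matrix, mwr)
  if (stats::sd(td) == 0) return(0)
  stats::cor(td, yields)^2
}

#' Calibrate the MWR row against the lowest yield quartile
#'
#' Maximizes the squared Pearson correlation between the total rainfall
#' deficit and the simulated yield over the lowest-quartile runs, subject to
#' every MWR entry being >= 0. The optimizer is multi-start bounded
#' quasi-Newton (`optim` L-BFGS-B) from the supplied start plus jittered
#' copies, with a Nelder-Mead polish of the best iterate; the multi-start
#' order is fixed by `seed`, so results are deterministic. After
#' optimization, any MWR entry at or below the minimum observed rainfall of
#' its dekad is snapped to the smallest equivalent value (zero), resolving
#' flat directions of the objective.
#'
#' @param runs A `run_table` subset for one pixel x soil: the lowest yield
#'   quartile (see [lowest_quartile()]); must contain `dekad_*` columns and
#'   `yield`.
#' @param init Starting MWR vector; default [initial_mwr()] of `runs`.
#' @param n_starts Number of optimizer starts (>= 1, default 8): the supplied
#'   start, three rainfall-quantile starts, then uniform random starts.
#' @param seed Seed fixing the jitter of the extra starts.
#' @param mwr_max Upper bound on the MWR entries (mm/dekad): a scalar, or
#'   a vector with one bound per dekad — typically the crop's per-dekad
#'   water demand. Default 80, roughly the potential evapotranspiration of
#'   a tropical crop over ten days. A minimum water requirement above what
#'   the crop could ever use is physically meaningless, and the bound keeps
#'   the optimizer out of the degenerate total-rainfall solution where
#'   every dekad's MWR exceeds every observed rainfall.
#' @param maxit Iteration cap per start.
#' @param tol Convergence tolerance on the objective.
#' @return A `calibration_result` list: `mwr` (optimized row, >= 0),
#'   `r_squared` (objective at the optimum), `rainfall_index_mm`
#'   (sum of the MWRs) and `diagnostics` (per-start objectives, convergence
#'   codes, iteration counts).
#' @export
calibrate_mwr <- function(runs, init = NULL, n_starts = 8L, seed = 1L,
                          mwr_max = 80, maxit = 500L, tol = 1e-8) {
  rain <- dekad_matrix(runs)
  yields <- runs$yield
  if (nrow(rain) < 3L) stop("need >= 3 runs to calibrate", call. = FALSE)
  if (stats::sd(yields) == 0) {
    stop("degenerate objective: zero yield variance in the subset", call. = FALSE)
  }
  if (is.null(init)) init <- initial_mwr(runs)
  init <- validate_mwr(init)
  if (length(init) != ncol(rain)) {
    stop("`init` length must equal the dekad count", call. = FALSE)
  }

  mwr_max <- rep_len(as.numeric(mwr_max), ncol(rain))
  if (any(!is.finite(mwr_max)) || any(mwr_max < 0)) {
    stop("`mwr_max` entries must be finite and >= 0", call. = FALSE)
  }
  init <- pmin(init, mwr_max)
  neg_obj <- function(m) -deficit_objective(m, rain, yields)
  # beyond the largest observed rainfall the objective is flat anyway
  upper <- pmin(apply(rain, 2L, max) + 1, mwr_max)

  # Fixed-order multi-start: the supplied init, rainfall quantiles of the
  # subset (median, upper quartile, max: the objective surface has distinct
  # basins at small and at large MWR), then uniform random starts.
  set.seed(as.integer(seed))
  starts <- list(init,
                 apply(rain, 2L, stats::median),
                 apply(rain, 2L, stats::quantile, probs = 0.75),
                 apply(rain, 2L, max))
  scale <- pmax(apply(rain, 2L, stats::sd), 5)
  starts <- lapply(starts, function(s) pmin(pmax(s, 0), upper))
  while (length(starts) < n_starts) {
    starts[[length(starts) + 1L]] <- stats::runif(length(init), 0, upper)
  }
  starts <- starts[seq_len(max(n_starts, 1L))]

  fits <- vector("list", length(starts))
  diag_obj <- numeric(length(starts))
  diag_conv <- integer(length(starts))
  diag_iter <- integer(length(starts))
  for (s in seq_along(starts)) {
    fit <- suppressWarnings(stats::optim(
      starts[[s]], neg_obj, method = "L-BFGS-B",
      lower = rep(0, length(init)), upper = upper,
      control = list(maxit = maxit, factr = tol / .Machine$double.eps)
    ))
    diag_obj[s] <- -fit$value
    diag_conv[s] <- fit$convergence
    diag_iter[s] <- fit$counts[["function"]]
    fits[[s]] <- fit
  }
  best <- fits[[which.min(vapply(fits, `[[`, 0, "value"))]]
  # derivative-free polish: the objective has min() kinks
  polish <- suppressWarnings(stats::optim(
    best$par, function(m) neg_obj(pmin(pmax(m, 0), upper)),
    method = "Nelder-Mead",
    control = list(maxit = maxit, reltol = tol)
  ))
  if (polish$value < best$value) {
    best <- polish
    best$par <- pmin(pmax(best$par, 0), upper)
    fits[[length(fits) + 1L]] <- best
  }

  # smallest-index tie rule: among starts whose objective ties the best
  # (within tol of the maximum), keep the most parsimonious MWR row —
  # the one with the smallest rainfall index (sum of entries)
  objs <- -vapply(fits, `[[`, 0, "value")
  tied <- which(objs >= max(objs) - 1e-6)
  sums <- vapply(fits[tied], function(f) sum(pmax(f$par, 0)), 0)
  best <- fits[[tied[which.min(sums)]]]

  mwr <- pmin(pmax(best$par, 0), upper)
  # objective never worse than at the supplied start
  if (-best$value < deficit_objective(init, rain, yields)) {
    mwr <- init
  }
  # canonical representative on flat directions: an entry at or below the
  # dekad's minimum rainfall produces zero deficit everywhere — snap to 0
  min_rain <- apply(rain, 2L, min)
  mwr[mwr <= min_rain] <- 0

  obj <- deficit_objective(mwr, rain, yields)
  structure(
    list(mwr = mwr,
         r_squared = obj,
         rainfall_index_mm = sum(mwr),
         diagnostics = list(start_objectives = diag_obj,
                            convergence = diag_conv,
                            evaluations = diag_iter,
                            n_starts = length(starts),
                            converged = any(diag_conv == 0L))),
    class = "calibration_result"
  )
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result>\n")
  cat("  MWR (mm):", paste(format(round(x$mwr, 1), trim = TRUE), collapse = " "), "\n")
  cat(sprintf("  rainfall index: %.1f mm;  R^2 (lowest quartile): %.3f\n",
              x$rainfall_index_mm, x$r_squared))
  invisible(x)
}

#' Serialize / read a calibration result as JSON
#'
#' @param result A `calibration_result`.
#' @param path File path.
#' @return `read_calibration_json` returns a `calibration_result`;
#'   `write_calibration_json` returns `path` invisibly.
#' @export
write_calibration_json <- function(result, path) {
  jsonlite::write_json(unclass(result), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_calibration_json
#' @export
read_calibration_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$mwr <- as.numeric(x$mwr)
  structure(x, class = "calibration_result")
}
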