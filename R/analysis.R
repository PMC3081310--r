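#' Arithmetic mean of replicate time series
#'
#' Element-wise arithmetic mean of every sampled statistic across replicate
#' runs sharing one sampling grid.  `mean_rate` is averaged over the runs in
#' which it is defined (a run with zero census contributes nothing at that
#' sample).  Per-sample standard deviations are appended as `*_sd` columns.
#'
#' @param series_list List of sample data frames as produced by
#'   [simulate_run()] (columns `time`, `direction`, `census`, `mean_rate`,
#'   `mean_rate_change`).
#' @return One data frame on the shared grid with averaged columns plus
#'   `census_sd`, `mean_rate_sd`, `mean_rate_change_sd`.
#' @export
average_runs <- function(series_list) {
  stopifnot(length(series_list) >= 1L)
  ref <- series_list[[1L]]
  for (s in series_list[-1L]) {
    if (nrow(s) != nrow(ref) || any(s$time != ref$time) ||
        any(s$direction != ref$direction))
      stop("all series must share the same sampling grid", call. = FALSE)
  }
  fields <- c("census", "mean_rate", "mean_rate_change")
  out <- ref[c("time", "direction")]
  for (f in fields) {
    mat <- vapply(series_list, function(s) as.numeric(s[[f]]),
                  numeric(nrow(ref)))
    mat <- matrix(mat, nrow = nrow(ref))
    out[[f]] <- rowMeans(mat, na.rm = TRUE)
    out[[f]][is.nan(out[[f]])] <- NA_real_
    out[[paste0(f, "_sd")]] <- apply(mat, 1L, stats::sd, na.rm = TRUE)
  }
  # keep averaged columns ahead of the sd columns
  out[c("time", "direction", fields, paste0(fields, "_sd"))]
}

#' Log-linear decline slope of a subpopulation
#'
#' The decline of the losing subpopulation in a full-environment competition
#' is roughly exponential, so its fate is summarized by an ordinary
#' least-squares fit of `ln(census)` against simulation time.  Samples with
#' zero census are excluded (the log is undefined there and the fit targets
#' the visible decline).  A slope indistinguishable from zero indicates
#' coexistence; a strictly negative slope indicates that the subpopulation
#' is being driven out.
#'
#' @param series A samples data frame (per-run or run-averaged).
#' @param direction Which subpopulation to fit (default `"reverse"`).
#' @param temperature,mutation Optional annotations carried into the result.
#' @return A data frame of class `"decline_fit"` with one row: columns
#'   `temperature`, `mutation`, `slope` (per time step), `intercept`,
#'   `n_points`.
#' @export
log_decline_slope <- function(series, direction = "reverse",
                              temperature = NA_real_, mutation = NA) {
  direction <- match.arg(direction, DIRECTIONS)
  sub <- series[series$direction == direction & series$census > 0, ]
  if (nrow(sub) < 2L)
    stop(structure(class = c("dirpol_undefined_result", "error", "condition"),
                   list(message = paste0("fewer than 2 positive-census ",
                                         "samples for direction \"",
                                         direction, "\""),
                        call = sys.call(-1))))
  fit <- stats::lm(log(census) ~ time, data = sub)
  out <- data.frame(temperature = temperature,
                    mutation = mutation,
                    slope = unname(coef(fit)[2L]),
                    intercept = unname(coef(fit)[1L]),
                    n_points = nrow(sub))
  class(out) <- c("decline_fit", "data.frame")
  out
}

#' Decline slopes across a set of ensembles
#'
#' Computes [log_decline_slope()] of the reverse subpopulation on the
#' run-averaged series of each ensemble and tabulates the slopes by
#' simulation temperature and mutation flag.  An ensemble whose reverse
#' census never yields two positive samples is reported with an `NA` slope.
#'
#' @param ensembles List of `sim_ensemble` objects (see [run_ensemble()]).
#' @param direction Subpopulation to fit (default `"reverse"`).
#' @return Data frame with columns `temperature`, `mutation`, `slope`,
#'   `intercept`, `n_points`, ordered by temperature then mutation flag.
#' @export
slope_vs_temperature <- function(ensembles, direction = "reverse") {
  stopifnot(length(ensembles) >= 1L)
  rows <- lapply(ensembles, function(ens) {
    stopifnot(inherits(ens, "sim_ensemble"))
    cfg <- ens$spec$config
    tryCatch(
      log_decline_slope(ens$averaged, direction,
                        temperature = cfg$temperature,
                        mutation = cfg$mutation_enabled),
      dirpol_undefined_result = function(e) {
        data.frame(temperature = cfg$temperature,
                   mutation = cfg$mutation_enabled,
                   slope = NA_real_, intercept = NA_real_, n_points = 0L)
      })
  })
  out <- do.call(rbind, lapply(rows, as.data.frame))
  out <- out[order(out$temperature, out$mutation), ]
  rownames(out) <- NULL
  out
}

#' Mean generational polymerase-rate change
#'
#' Mean of `|daughter rate - mother rate|` over the births recorded in a
#' window of simulation time; 0 when there were no births.  With inheritance
#' purely random and uniform on the integer rates 1..10 the expected value
#' is 3.3, so values approaching that ceiling indicate that the thermal
#' error rate has destroyed heritability of the rate.
#'
#' @param births Birth records (`step`, `direction`, `delta`) from
#'   [simulate_run()], or the stacked records of several runs.
#' @param window Optional `c(first, last)` step range (inclusive); default
#'   all births.
#' @param direction Optional direction filter.
#' @return A single number in `[0, rate_max - rate_min]`.
#' @export
generational_rate_change <- function(births, window = NULL,
                                     direction = NULL) {
  keep <- rep(TRUE, nrow(births))
  if (!is.null(window))
    keep <- keep & births$step >= window[1L] & births$step <= window[2L]
  if (!is.null(direction))
    keep <- keep & births$direction == match.arg(direction, DIRECTIONS)
  deltas <- births$delta[keep]
  if (length(deltas) == 0L) return(0)
  mean(abs(deltas))
}

#' Run the full temperature sweep and tabulate decline slopes
#'
#' Convenience wrapper: builds [preset_temperature_sweep()] scenarios for
#' each requested mutation flag, runs each with [run_ensemble()], and
#' returns the combined [slope_vs_temperature()] table.
#'
#' @param mutation_flags Logical vector of mutation settings to sweep
#'   (default both `TRUE` and `FALSE`).
#' @param temps Temperatures to sweep.
#' @param ... Overrides passed to [preset_full_competition()].
#' @param engine Passed to [run_ensemble()].
#' @return A slope table as from [slope_vs_temperature()].
#' @export
run_temperature_sweep <- function(mutation_flags = c(TRUE, FALSE),
                                  temps = seq(0.10, 0.60, by = 0.05),
                                  ..., engine = "cpp") {
  ensembles <- list()
  for (flag in mutation_flags) {
    specs <- preset_temperature_sweep(mutation_enabled = flag,
                                      temps = temps, ...)
    ensembles <- c(ensembles,
                   lapply(specs, run_ensemble, engine = engine))
  }
  slope_vs_temperature(ensembles)
}
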