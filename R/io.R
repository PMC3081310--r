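ts_columns <- c("time", "direction", "census", "mean_rate",
                "mean_rate_change")

#' Write / read a tidy time-series table
#'
#' Time series travel as UTF-8, tab-delimited text with a header row:
#' one row per sample time and direction (plus a leading `run` column for
#' stacked per-run tables, and `*_sd` columns for run-averaged tables).
#' The round trip through `write_timeseries()` and `read_timeseries()` is
#' lossless.
#'
#' @param series A samples data frame containing at least the columns
#'   `time`, `direction`, `census`, `mean_rate`, `mean_rate_change`.
#' @param path File path.
#' @return `write_timeseries()` returns `path` invisibly;
#'   `read_timeseries()` returns the data frame.
#' @export
write_timeseries <- function(series, path) {
  missing_cols <- setdiff(ts_columns, names(series))
  if (length(missing_cols) > 0)
    stop("series is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  utils::write.table(series, file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path) {
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = TRUE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(ts_columns, names(raw))
  if (length(missing_cols) > 0)
    stop(sprintf("%s: line 1: missing column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  numeric_cols <- setdiff(names(raw), "direction")
  for (cc in numeric_cols) {
    vals <- suppressWarnings(as.numeric(raw[[cc]]))
    bad <- which(is.na(vals) &
                 !(is.na(raw[[cc]]) | raw[[cc]] %in% c("NA", "")))
    if (length(bad) > 0)
      stop(sprintf("%s: line %d: non-numeric value \"%s\" in column %s",
                   path, bad[1L] + 1L, raw[[cc]][bad[1L]], cc),
           call. = FALSE)
    raw[[cc]] <- vals
  }
  bad_dir <- which(!(raw$direction %in% DIRECTIONS))
  if (length(bad_dir) > 0)
    stop(sprintf("%s: line %d: unknown direction \"%s\"", path,
                 bad_dir[1L] + 1L, raw$direction[bad_dir[1L]]),
         call. = FALSE)
  int_cols <- intersect(c("run", "time", "census", "n_points"), names(raw))
  for (cc in int_cols) raw[[cc]] <- as.integer(raw[[cc]])
  raw
}

#' Run manifest
#'
#' A manifest records everything needed to regenerate a run's outputs
#' byte-for-byte: the scenario name, the fully resolved configuration
#' (including the model-variant switches `rate_factor` and `cull_epsilon`),
#' the master seed, the derived per-run seeds, and the artifact paths.  It
#' round-trips losslessly through JSON.
#'
#' @param spec A [scenario_spec()].
#' @param files Named character vector / list of artifact paths.
#' @return A list of class `"run_manifest"`.
#' @export
build_manifest <- function(spec, files = list()) {
  stopifnot(inherits(spec, "scenario_spec"))
  cfg <- spec$config
  man <- list(
    scenario = spec$name,
    config = unclass(cfg),
    seeding = as.data.frame(unclass(spec$seeding),
                            stringsAsFactors = FALSE),
    master_seed = cfg$master_seed,
    run_seeds = cfg$master_seed + seq_len(cfg$n_runs) - 1L,
    files = as.list(files),
    package_version = as.character(utils::packageVersion("dirpol"))
  )
  class(man) <- "run_manifest"
  man
}

#' @rdname build_manifest
#' @param manifest A `run_manifest`.
#' @param path File path for the JSON manifest.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "run_manifest"))
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname build_manifest
#' @export
read_manifest <- function(path) {
  man <- jsonlite::read_json(path, simplifyVector = TRUE)
  man$config <- as.list(man$config)
  man$seeding <- as.data.frame(man$seeding, stringsAsFactors = FALSE)
  class(man) <- "run_manifest"
  man
}

#' Rebuild the scenario described by a manifest
#'
#' @param manifest A `run_manifest` (possibly read back from JSON).
#' @return The [scenario_spec()] it describes.
#' @export
manifest_scenario <- function(manifest) {
  stopifnot(inherits(manifest, "run_manifest"))
  cfg <- manifest$config
  config <- sim_config(
    temperature = cfg$temperature, capacity = cfg$capacity,
    genome_length = cfg$genome_length, rate_min = cfg$rate_min,
    rate_max = cfg$rate_max, error_tolerance = cfg$error_tolerance,
    mutation_enabled = cfg$mutation_enabled,
    cull_epsilon = cfg$cull_epsilon, n_steps = cfg$n_steps,
    sample_every = cfg$sample_every, n_runs = cfg$n_runs,
    master_seed = cfg$master_seed, rate_factor = cfg$rate_factor)
  plan <- seeding_plan(manifest$seeding$direction, manifest$seeding$rate,
                       manifest$seeding$count)
  scenario_spec(manifest$scenario, config, plan)
}
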