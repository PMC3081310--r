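#' Simulation configuration
#'
#' Collects every model constant and experiment knob in one validated record.
#'
#' @param temperature Dimensionless simulation temperature `T` (the folded
#'   `kT / deltaG` factor of the Boltzmann probabilities).  Must be positive.
#'   Values between 0.10 and 0.60 span the regimes of interest: near 0.1
#'   hydrolysis and misincorporation are vanishingly rare, near 0.6 a slow
#'   reverse polymerase can be stalled almost every step.
#' @param capacity Carrying capacity `K` of the environment (default 1000).
#' @param genome_length Genome size `L` in nucleotides (default 1000).
#' @param rate_min,rate_max Bounds of the heritable integer polymerase rate,
#'   in nucleotides per time step (defaults 1 and 10).
#' @param error_tolerance Fraction of erroneous inclusions per genome at
#'   which the inherited-rate perturbation saturates (`e_max`, default 0.34).
#' @param mutation_enabled If `FALSE` the misincorporation probability is
#'   exactly zero, so daughters always inherit their mother's rate and the
#'   rate can evolve only through selection among the seeded lineages.
#' @param cull_epsilon Offset `eps` in the culling probability
#'   `min(1, 1 / (K - N + eps))`; the default 1 makes at least one removal
#'   certain when the population is at capacity.
#' @param n_steps Number of simulation time steps per run.
#' @param sample_every Sampling interval in steps; population statistics are
#'   recorded at step 0 and every `sample_every` steps thereafter.
#' @param n_runs Number of replicate runs in an ensemble (default 10).
#' @param master_seed Integer master seed; run `i` of an ensemble uses
#'   `master_seed + i - 1`.
#' @param rate_factor Form of the monotone rate factor `g(r)` that multiplies
#'   the thermal misincorporation term: `"sqrt"` (default) treats polymerase
#'   rate as volumetric flux through a cylindrical tube whose radius sets the
#'   geometric fidelity constraint, giving `g(r) = sqrt(r / rate_max)`;
#'   `"linear"` (`g(r) = r / rate_max`) is retained for sensitivity checks.
#'
#' @return A list of class `"sim_config"`.
#' @examples
#' cfg <- sim_config(temperature = 0.3, n_steps = 1000, sample_every = 5)
#' cfg$capacity
#' @export
sim_config <- function(temperature,
                       capacity = 1000L,
                       genome_length = 1000L,
                       rate_min = 1L,
                       rate_max = 10L,
                       error_tolerance = 0.34,
                       mutation_enabled = TRUE,
                       cull_epsilon = 1,
                       n_steps = 50000L,
                       sample_every = 50L,
                       n_runs = 10L,
                       master_seed = 1L,
                       rate_factor = c("sqrt", "linear")) {
  rate_factor <- match.arg(rate_factor)
  cfg <- list(
    temperature = as.numeric(temperature),
    capacity = as.integer(capacity),
    genome_length = as.integer(genome_length),
    rate_min = as.integer(rate_min),
    rate_max = as.integer(rate_max),
    error_tolerance = as.numeric(error_tolerance),
    mutation_enabled = isTRUE(mutation_enabled),
    cull_epsilon = as.numeric(cull_epsilon),
    n_steps = as.integer(n_steps),
    sample_every = as.integer(sample_every),
    n_runs = as.integer(n_runs),
    master_seed = as.integer(master_seed),
    rate_factor = rate_factor
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.finite(cfg$temperature) || cfg$temperature <= 0)
    stop("`temperature` must be a positive number", call. = FALSE)
  if (is.na(cfg$capacity) || cfg$capacity < 1L)
    stop("`capacity` must be a positive integer", call. = FALSE)
  if (is.na(cfg$genome_length) || cfg$genome_length < 1L)
    stop("`genome_length` must be a positive integer", call. = FALSE)
  if (is.na(cfg$rate_min) || is.na(cfg$rate_max) ||
      cfg$rate_min < 1L || cfg$rate_min > cfg$rate_max)
    stop("rate bounds must satisfy 1 <= rate_min <= rate_max", call. = FALSE)
  if (!is.finite(cfg$error_tolerance) ||
      cfg$error_tolerance <= 0 || cfg$error_tolerance > 1)
    stop("`error_tolerance` must lie in (0, 1]", call. = FALSE)
  if (!is.finite(cfg$cull_epsilon) || cfg$cull_epsilon <= 0)
    stop("`cull_epsilon` must be positive", call. = FALSE)
  if (is.na(cfg$n_steps) || cfg$n_steps < 1L)
    stop("`n_steps` must be a positive integer", call. = FALSE)
  if (is.na(cfg$sample_every) || cfg$sample_every < 1L)
    stop("`sample_every` must be a positive integer", call. = FALSE)
  if (is.na(cfg$n_runs) || cfg$n_runs < 1L)
    stop("`n_runs` must be a positive integer", call. = FALSE)
  if (is.na(cfg$master_seed))
    stop("`master_seed` must be an integer", call. = FALSE)
  invisible(cfg)
}

check_rate <- function(rate, cfg) {
  if (any(rate < cfg$rate_min | rate > cfg$rate_max))
    stop(sprintf("polymerase rate must lie in [%d, %d]",
                 cfg$rate_min, cfg$rate_max), call. = FALSE)
  invisible(as.integer(rate))
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  temperature      %.3f\n", x$temperature))
  cat(sprintf("  capacity K       %d\n", x$capacity))
  cat(sprintf("  genome length L  %d\n", x$genome_length))
  cat(sprintf("  rate bounds      [%d, %d]\n", x$rate_min, x$rate_max))
  cat(sprintf("  error tolerance  %.2f\n", x$error_tolerance))
  cat(sprintf("  mutation         %s\n",
              if (x$mutation_enabled) "enabled" else "disabled"))
  cat(sprintf("  rate factor      %s\n", x$rate_factor))
  cat(sprintf("  steps x runs     %d x %d (sample every %d)\n",
              x$n_steps, x$n_runs, x$sample_every))
  cat(sprintf("  master seed      %d\n", x$master_seed))
  invisible(x)
}
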