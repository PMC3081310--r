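#' Seeding plan
#'
#' Describes the founding population as (direction, rate, count) entries.
#'
#' @param direction Character vector of `"forward"` / `"reverse"`.
#' @param rate Integer vector of polymerase rates.
#' @param count Integer vector of organism counts (recycled).
#' @return A data frame of class `"seeding_plan"` with columns `direction`,
#'   `rate`, `count`.
#' @examples
#' # one forward organism at each rate 1..10, mean rate 5.5
#' plan <- seeding_plan("forward", 1:10, 1)
#' plan_mean_rate(plan)
#' @export
seeding_plan <- function(direction, rate, count = 1L) {
  plan <- data.frame(direction = as.character(direction),
                     rate = as.integer(rate),
                     count = as.integer(count),
                     stringsAsFactors = FALSE)
  if (!all(plan$direction %in% DIRECTIONS))
    stop("direction must be \"forward\" or \"reverse\"", call. = FALSE)
  if (any(plan$count < 0L))
    stop("counts must be non-negative", call. = FALSE)
  class(plan) <- c("seeding_plan", "data.frame")
  plan
}

validate_seeding_plan <- function(plan, config) {
  if (!inherits(plan, "seeding_plan"))
    stop("`plan` must be a seeding_plan()", call. = FALSE)
  check_rate(plan$rate, config)
  if (plan_total(plan) > config$capacity)
    stop("seeding plan exceeds the carrying capacity", call. = FALSE)
  invisible(plan)
}

# one row per organism, in plan order (the order in which seeding draws the
# initial genome progress)
expand_plan <- function(plan) {
  idx <- rep(seq_len(nrow(plan)), times = plan$count)
  data.frame(direction = plan$direction[idx], rate = plan$rate[idx],
             stringsAsFactors = FALSE)
}

#' @rdname seeding_plan
#' @param plan A `seeding_plan`.
#' @export
plan_total <- function(plan) sum(plan$count)

#' @rdname seeding_plan
#' @export
plan_mean_rate <- function(plan) {
  if (plan_total(plan) == 0L) return(NA_real_)
  sum(plan$rate * plan$count) / plan_total(plan)
}

#' Seed an environment from a plan
#'
#' Creates one organism per planned entry, all in the replicating state, each
#' with an initial copied count drawn uniformly from `{0, ..., L - 1}` so
#' that first divisions are desynchronized.  Daughters born later always
#' start from 0.
#'
#' @param plan A [seeding_plan()] whose total does not exceed the capacity.
#' @param config A [sim_config()].
#' @return A [new_environment()] holding the founding population.
#' @export
seed_population <- function(plan, config) {
  validate_sim_config(config)
  validate_seeding_plan(plan, config)
  env <- new_environment(config)
  expanded <- expand_plan(plan)
  L <- config$genome_length
  orgs <- vector("list", nrow(expanded))
  for (i in seq_len(nrow(expanded))) {
    progress <- floor(runif(1) * L)
    orgs[[i]] <- new_organism(expanded$direction[i], expanded$rate[i],
                              copied_count = progress)
  }
  env$organisms <- orgs
  env
}

#' Scenario specification
#'
#' Binds a configuration to a seeding plan under a name.
#'
#' @param name Scenario name.
#' @param config A [sim_config()]; `sample_every` must divide `n_steps`.
#' @param seeding A [seeding_plan()].
#' @return A list of class `"scenario_spec"`.
#' @export
scenario_spec <- function(name, config, seeding) {
  validate_sim_config(config)
  validate_seeding_plan(seeding, config)
  if (config$n_steps %% config$sample_every != 0L)
    stop("`sample_every` must divide `n_steps`", call. = FALSE)
  spec <- list(name = name, config = config, seeding = seeding)
  class(spec) <- "scenario_spec"
  spec
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("Scenario \"%s\": %d organisms seeded (mean rate %.2f)\n",
              x$name, plan_total(x$seeding), plan_mean_rate(x$seeding)))
  print(x$config)
  invisible(x)
}

# shared override plumbing for the presets
preset_config <- function(temperature, n_steps, sample_every,
                          capacity, genome_length, n_runs,
                          mutation_enabled, master_seed, ...) {
  sim_config(temperature = temperature, capacity = capacity,
             genome_length = genome_length, n_steps = n_steps,
             sample_every = sample_every, n_runs = n_runs,
             mutation_enabled = mutation_enabled,
             master_seed = master_seed, ...)
}

#' Isolated exponential growth scenario
#'
#' A single polymerase variety growing without competition: 10 organisms of
#' one direction, one at each integer rate 1..10 (mean seeded rate 5.5), run
#' for 5000 steps with statistics collected every 5 steps.
#'
#' @param direction `"forward"` or `"reverse"`.
#' @param temperature Simulation temperature.
#' @param capacity,genome_length,n_steps,sample_every,n_runs,mutation_enabled,master_seed
#'   Overrides of the standard design, for desk-scale replicas.
#' @param ... Further arguments passed to [sim_config()].
#' @return A [scenario_spec()].
#' @export
preset_isolated_growth <- function(direction, temperature,
                                   capacity = 1000L, genome_length = 1000L,
                                   n_steps = 5000L, sample_every = 5L,
                                   n_runs = 10L, mutation_enabled = TRUE,
                                   master_seed = 1L, ...) {
  cfg <- preset_config(temperature, n_steps, sample_every, capacity,
                       genome_length, n_runs, mutation_enabled,
                       master_seed, ...)
  plan <- seeding_plan(direction, seq(cfg$rate_min, cfg$rate_max), 1L)
  scenario_spec(sprintf("isolated-growth-%s", direction), cfg, plan)
}

#' Competition during exponential growth scenario
#'
#' Both varieties growing from a small mixed seed: 100 organisms, 50 forward
#' and 50 reverse, 5 per (direction, rate) pair (per-direction mean rate
#' 5.5), run for 50000 steps sampled every 50.
#'
#' @inheritParams preset_isolated_growth
#' @export
preset_competition_growth <- function(temperature,
                                      capacity = 1000L, genome_length = 1000L,
                                      n_steps = 50000L, sample_every = 50L,
                                      n_runs = 10L, mutation_enabled = TRUE,
                                      master_seed = 1L, ...) {
  cfg <- preset_config(temperature, n_steps, sample_every, capacity,
                       genome_length, n_runs, mutation_enabled,
                       master_seed, ...)
  rates <- seq(cfg$rate_min, cfg$rate_max)
  plan <- seeding_plan(rep(DIRECTIONS, each = length(rates)),
                       rep(rates, times = 2L), 5L)
  scenario_spec("competition-growth", cfg, plan)
}

#' Competition in a full environment scenario
#'
#' Both varieties seeded at carrying capacity: half forward, half reverse,
#' split evenly over the integer rates (at the standard size, 50 organisms
#' per (direction, rate) pair, 1000 in total).  When `capacity` is
#' overridden, the per-pair count scales as `capacity / (2 * n_rates)` so
#' the environment still starts exactly full; the override must make that
#' ratio a whole number.  Runs 50000 steps sampled every 50.
#'
#' @inheritParams preset_isolated_growth
#' @export
preset_full_competition <- function(temperature,
                                    capacity = 1000L, genome_length = 1000L,
                                    n_steps = 50000L, sample_every = 50L,
                                    n_runs = 10L, mutation_enabled = TRUE,
                                    master_seed = 1L, ...) {
  cfg <- preset_config(temperature, n_steps, sample_every, capacity,
                       genome_length, n_runs, mutation_enabled,
                       master_seed, ...)
  rates <- seq(cfg$rate_min, cfg$rate_max)
  per_pair <- cfg$capacity / (2L * length(rates))
  if (per_pair != floor(per_pair) || per_pair < 1)
    stop("`capacity` must be a positive multiple of twice the number of rates",
         call. = FALSE)
  plan <- seeding_plan(rep(DIRECTIONS, each = length(rates)),
                       rep(rates, times = 2L), as.integer(per_pair))
  scenario_spec("full-competition", cfg, plan)
}

#' Temperature sweep of full-environment competition
#'
#' Full-competition scenarios at temperatures 0.10 to 0.60 in 0.05
#' increments (11 scenarios), all sharing one mutation flag.
#'
#' @param mutation_enabled Logical mutation flag applied to every scenario.
#' @param temps Numeric vector of temperatures.
#' @param ... Passed to [preset_full_competition()].
#' @return A list of [scenario_spec()] objects, ordered by temperature.
#' @export
preset_temperature_sweep <- function(mutation_enabled = TRUE,
                                     temps = seq(0.10, 0.60, by = 0.05),
                                     ...) {
  lapply(sort(temps), function(tt) {
    preset_full_competition(temperature = tt,
                            mutation_enabled = mutation_enabled, ...)
  })
}

#' Run an ensemble of replicate simulations
#'
#' Executes `n_runs` independent runs of a scenario (run `i` seeded with
#' `master_seed + i - 1`) and averages the sampled statistics arithmetically
#' across runs with [average_runs()].
#'
#' @param spec A [scenario_spec()].
#' @param engine Passed to [simulate_run()].
#' @return A list of class `"sim_ensemble"` with elements `spec`, `runs`
#'   (list of [simulate_run()] results), `samples` (all per-run samples
#'   stacked with a `run` column) and `averaged` (the run-averaged series,
#'   with per-sample standard deviations).
#' @export
run_ensemble <- function(spec, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(inherits(spec, "scenario_spec"))
  cfg <- spec$config
  runs <- lapply(seq_len(cfg$n_runs), function(i) {
    simulate_run(cfg, spec$seeding, seed = cfg$master_seed + i - 1L,
                 engine = engine)
  })
  samples <- do.call(rbind, lapply(seq_along(runs), function(i) {
    cbind(run = i, runs[[i]]$samples)
  }))
  rownames(samples) <- NULL
  averaged <- average_runs(lapply(runs, function(r) r$samples))
  out <- list(spec = spec, runs = runs, samples = samples,
              averaged = averaged)
  class(out) <- "sim_ensemble"
  out
}

#' @export
print.sim_ensemble <- function(x, ...) {
  cat(sprintf("Ensemble \"%s\": %d runs, T = %.2f, mutation %s\n",
              x$spec$name, length(x$runs), x$spec$config$temperature,
              if (x$spec$config$mutation_enabled) "on" else "off"))
  last <- x$averaged[x$averaged$time == max(x$averaged$time), ]
  cat(sprintf("  mean final census: forward %.1f, reverse %.1f\n",
              last$census[last$direction == "forward"],
              last$census[last$direction == "reverse"]))
  invisible(x)
}
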