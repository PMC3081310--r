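#' Spontaneous triphosphate hydrolysis probability
#'
#' Probability that a nucleotide triphosphate needed for the next addition
#' has lost its activating triphosphate group, drawn once before every
#' attempted addition.  For a forward polymerase the probability is the bare
#' Boltzmann factor `exp(-1/T)`: the incoming monomer pool is assumed
#' pre-equilibrated, so the probability does not depend on how long the
#' polymerase waits.  For a reverse polymerase the activated group sits on
#' the growing chain itself and is exposed for a time inversely proportional
#' to the polymerase rate, so the factor is scaled by `rate_max / rate` and
#' clamped to 1.  The two strategies coincide at `rate = rate_max`.
#'
#' @param direction `"forward"` or `"reverse"`.
#' @param rate Integer polymerase rate in `[rate_min, rate_max]`.
#' @param config A [sim_config()].
#' @return A probability in `[0, 1]`.
#' @examples
#' cfg <- sim_config(temperature = 0.5, n_steps = 1, sample_every = 1)
#' hydrolysis_probability("forward", 5, cfg)   # exp(-2)
#' hydrolysis_probability("reverse", 1, cfg)   # 10 * exp(-2), clamped at 1
#' @export
hydrolysis_probability <- function(direction, rate, config) {
  validate_sim_config(config)
  rate <- check_rate(rate, config)
  base <- exp(-1 / config$temperature)
  if (dir_code(direction) == 0L) base
  else min(1, (config$rate_max / rate) * base)
}

#' Erroneous nucleotide inclusion probability
#'
#' Probability that a successful addition incorporates a mismatched
#' nucleotide.  Two factors multiply: a hydrogen-bonding discrimination term
#' `exp(-2/T)` (the free-energy gap between a Watson-Crick pair and a
#' mismatch is twice that of the spontaneous hydrolysis reaction) and a
#' monotone rate factor `g(rate)` normalized so `g(rate_max) = 1`, encoding
#' the fidelity cost of relaxing the geometric constraint needed to
#' polymerize faster (see `rate_factor` in [sim_config()]).  When
#' `mutation_enabled` is `FALSE` the probability is exactly zero.
#'
#' @inheritParams hydrolysis_probability
#' @return A probability in `[0, 1]`.
#' @export
error_probability <- function(rate, config) {
  validate_sim_config(config)
  rate <- check_rate(rate, config)
  if (!config$mutation_enabled) return(0)
  g <- if (config$rate_factor == "sqrt") sqrt(rate / config$rate_max)
       else rate / config$rate_max
  exp(-2 / config$temperature) * g
}

#' Density-dependent culling probability
#'
#' Probability of removing (at least) one organism given the current census
#' `n_current`: `min(1, 1 / (K - n_current + eps))`.  With the default
#' `eps = 1` the probability is `1/(K+1)` in an empty environment and exactly
#' 1 at capacity, mimicking density-dependent growth inhibition.
#'
#' @param n_current Current number of organisms, `0 <= n_current <= K`.
#' @param config A [sim_config()].
#' @return A probability in `(0, 1]`.
#' @export
cull_probability <- function(n_current, config) {
  validate_sim_config(config)
  if (n_current < 0 || n_current > config$capacity)
    stop("`n_current` must lie in [0, capacity]", call. = FALSE)
  min(1, 1 / (config$capacity - n_current + config$cull_epsilon))
}

#' Rate inherited by a daughter genome
#'
#' The magnitude of the generational rate change grows with the fraction of
#' erroneous inclusions `E` made while copying the mother genome and
#' saturates at the error tolerance `e_max`:
#' `delta = round((rate_max - rate_min) * min(E / e_max, 1))`, rounded
#' half-away-from-zero.  The sign is drawn uniformly when both
#' `mother_rate + delta` and `mother_rate - delta` stay within the rate
#' bounds, forced when only one does, and drawn then clamped to the nearest
#' bound when neither does.  With mutation disabled the mother's rate is
#' returned unchanged and no random draw is consumed.
#'
#' @param mother_rate Integer rate encoded by the mother genome.
#' @param error_fraction Fraction `E = error_count / genome_length` in `[0, 1]`.
#' @param config A [sim_config()].
#' @return An integer rate in `[rate_min, rate_max]`.
#' @export
inherit_rate <- function(mother_rate, error_fraction, config) {
  validate_sim_config(config)
  mother_rate <- check_rate(mother_rate, config)
  if (error_fraction < 0 || error_fraction > 1)
    stop("`error_fraction` must lie in [0, 1]", call. = FALSE)
  if (!config$mutation_enabled) return(mother_rate)
  frac <- min(error_fraction / config$error_tolerance, 1)
  delta <- as.integer(floor((config$rate_max - config$rate_min) * frac + 0.5))
  if (delta == 0L) return(mother_rate)
  up <- mother_rate + delta
  down <- mother_rate - delta
  up_ok <- up <= config$rate_max
  down_ok <- down >= config$rate_min
  if (up_ok && down_ok) {
    if (runif(1) < 0.5) up else down
  } else if (up_ok) {
    up
  } else if (down_ok) {
    down
  } else {
    child <- if (runif(1) < 0.5) up else down
    min(config$rate_max, max(config$rate_min, child))
  }
}

#' Create an organism
#'
#' An organism is a finite state machine: in the `"replicating"` state its
#' polymerase adds nucleotides to a nascent genome copy; once the copy is
#' complete it switches to `"dividing"` and waits for room in the
#' environment.  The genome is a counter triple (length, nucleotides copied,
#' errors made) plus the encoded rate and direction it passes on.
#'
#' @param direction `"forward"` or `"reverse"`; immutable for the lineage.
#' @param rate Integer polymerase rate.
#' @param copied_count Nucleotides already added to the nascent copy.
#' @param parent_rate Rate of the mother's polymerase (equal to `rate` for
#'   seeded founders).
#' @return A list of class `"organism"`.
#' @export
new_organism <- function(direction, rate, copied_count = 0L,
                         parent_rate = rate) {
  org <- list(
    direction = match.arg(direction, DIRECTIONS),
    rate = as.integer(rate),
    copied_count = as.integer(copied_count),
    error_count = 0L,
    parent_rate = as.integer(parent_rate),
    state = "replicating"
  )
  class(org) <- "organism"
  org
}

#' Create an empty environment
#'
#' @param config A [sim_config()]; fixes the carrying capacity.
#' @return A list of class `"sim_environment"` with fields `capacity`,
#'   `organisms` (a list) and `time` (step counter, starts at 0).
#' @export
new_environment <- function(config) {
  validate_sim_config(config)
  env <- list(capacity = config$capacity, organisms = list(), time = 0L)
  class(env) <- "sim_environment"
  env
}

#' One polymerization time step for one organism
#'
#' Runs the per-step addition loop: up to `rate` iterations, each preceded by
#' a spontaneous-hydrolysis draw.  A forward polymerase skips the spoiled
#' addition and continues; a reverse polymerase halts for the rest of the
#' step (the generic stand-in for chain-terminus repair).  Each successful
#' addition increments the copied count and, with [error_probability()],
#' the error count (an erroneous nucleotide is still incorporated).  When the
#' copy reaches full genome length the organism switches to the dividing
#' state; it will not attempt division before the next time step.
#'
#' @param organism A replicating [new_organism()].
#' @param config A [sim_config()].
#' @return A list with the updated `organism` and the step tallies `added`,
#'   `errors` and `hydrolysis_events`.
#' @export
polymerize_step <- function(organism, config) {
  if (organism$state != "replicating")
    stop("polymerize_step() called on a dividing organism", call. = FALSE)
  p_h <- hydrolysis_probability(organism$direction, organism$rate, config)
  p_e <- error_probability(organism$rate, config)
  L <- config$genome_length
  added <- 0L; errors <- 0L; hydro <- 0L
  it <- 0L
  while (it < organism$rate && organism$copied_count < L) {
    it <- it + 1L
    if (runif(1) < p_h) {
      hydro <- hydro + 1L
      if (organism$direction == "forward") next else break
    }
    organism$copied_count <- organism$copied_count + 1L
    added <- added + 1L
    if (runif(1) < p_e) {
      organism$error_count <- organism$error_count + 1L
      errors <- errors + 1L
    }
    if (organism$copied_count == L) {
      organism$state <- "dividing"
      break
    }
  }
  list(organism = organism, added = added, errors = errors,
       hydrolysis_events = hydro)
}

#' Attempt division of a dividing organism
#'
#' If the environment is below capacity a daughter is created with the
#' mother's direction, a fresh genome, and a rate drawn by [inherit_rate()]
#' from the mother's encoded rate and the error fraction of the copy just
#' completed; the mother resets her counters and returns to the replicating
#' state with her own rate unchanged.  At capacity nothing happens and the
#' mother stays in the dividing state.
#'
#' @param env A [new_environment()] containing the organism.
#' @param index Position of the dividing organism in `env$organisms`.
#' @param config A [sim_config()].
#' @return A list with the updated `env`, the `daughter` (or `NULL`) and the
#'   signed generational rate change `delta` (or `NA`).
#' @export
attempt_division <- function(env, index, config) {
  org <- env$organisms[[index]]
  if (org$state != "dividing")
    stop("attempt_division() called on a replicating organism", call. = FALSE)
  if (length(env$organisms) >= env$capacity)
    return(list(env = env, daughter = NULL, delta = NA_integer_))
  child_rate <- inherit_rate(org$rate,
                             org$error_count / config$genome_length, config)
  daughter <- new_organism(org$direction, child_rate, 0L,
                           parent_rate = org$rate)
  org$copied_count <- 0L
  org$error_count <- 0L
  org$state <- "replicating"
  env$organisms[[index]] <- org
  env$organisms[[length(env$organisms) + 1L]] <- daughter
  list(env = env, daughter = daughter,
       delta = as.integer(child_rate - org$rate))
}

#' Density-dependent random culling
#'
#' Repeatedly draws against [cull_probability()] at the current census; each
#' success removes one organism chosen uniformly at random (any state) and
#' the probability is recomputed.  Stops at the first failed draw or when the
#' environment is empty.
#'
#' @param env A [new_environment()].
#' @param config A [sim_config()].
#' @return A list with the updated `env` and the number `removed`.
#' @export
apply_culling <- function(env, config) {
  removed <- 0L
  repeat {
    n <- length(env$organisms)
    if (n == 0L) break
    p <- cull_probability(n, config)
    if (runif(1) < p) {
      j <- floor(runif(1) * n) + 1
      # uniform removal by swap-with-last; order is irrelevant because the
      # action order is reshuffled every step
      env$organisms[[j]] <- env$organisms[[n]]
      env$organisms[[n]] <- NULL
      removed <- removed + 1L
    } else break
  }
  list(env = env, removed = removed)
}

# Fisher-Yates permutation consuming one uniform draw per swap; kept manual
# (not sample()) so the pure-R engine and the compiled engine consume the
# random stream identically.
shuffled_indices <- function(n) {
  perm <- seq_len(n)
  if (n >= 2L) {
    for (i in n:2) {
      j <- floor(runif(1) * i) + 1
      tmp <- perm[i]; perm[i] <- perm[j]; perm[j] <- tmp
    }
  }
  perm
}

#' Advance the environment by one time step
#'
#' Iterates the organisms present at the start of the step in a freshly
#' shuffled order (avoiding systematic first-mover advantage): replicating
#' organisms run [polymerize_step()], dividing organisms run
#' [attempt_division()].  Daughters born during the step take no action until
#' the next step, and an organism that completes its genome divides no
#' earlier than the next step.  [apply_culling()] then runs once and the
#' clock advances.
#'
#' @param env A [new_environment()].
#' @param config A [sim_config()].
#' @return A list with the updated `env` and per-step tallies: `added`,
#'   `errors`, `culled`, and `births` (a data frame with columns `step`,
#'   `direction`, `delta`).
#' @export
advance_time_step <- function(env, config) {
  n <- length(env$organisms)
  perm <- shuffled_indices(n)
  added <- 0L; errors <- 0L
  b_dir <- character(0); b_delta <- integer(0)
  step <- env$time + 1L
  for (i in perm) {
    org <- env$organisms[[i]]
    if (org$state == "replicating") {
      res <- polymerize_step(org, config)
      env$organisms[[i]] <- res$organism
      added <- added + res$added
      errors <- errors + res$errors
    } else {
      res <- attempt_division(env, i, config)
      env <- res$env
      if (!is.null(res$daughter)) {
        b_dir <- c(b_dir, res$daughter$direction)
        b_delta <- c(b_delta, res$delta)
      }
    }
  }
  cull <- apply_culling(env, config)
  env <- cull$env
  env$time <- step
  births <- data.frame(step = rep(step, length(b_delta)),
                       direction = b_dir, delta = b_delta,
                       stringsAsFactors = FALSE)
  list(env = env, added = added, errors = errors,
       culled = cull$removed, births = births)
}
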