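test_that("hydrolysis probability follows the Boltzmann factor and its rate scaling", {
  cfg <- tiny_config(temperature = 0.5)
  expect_equal(hydrolysis_probability("forward", 5, cfg), exp(-2))
  # forward value is rate-independent
  expect_equal(hydrolysis_probability("forward", 1, cfg),
               hydrolysis_probability("forward", 10, cfg))
  # reverse at maximum rate coincides with forward
  expect_equal(hydrolysis_probability("reverse", 10, cfg),
               hydrolysis_probability("forward", 10, cfg))
  # reverse >= forward, strictly above below the maximum rate
  for (r in 1:9)
    expect_gt(hydrolysis_probability("reverse", r, cfg),
              hydrolysis_probability("forward", r, cfg))
  # clamp: 10 * exp(-1/0.6) > 1
  cfg6 <- tiny_config(temperature = 0.6)
  expect_equal(hydrolysis_probability("reverse", 1, cfg6), 1)
  # vanishes as T -> 0+
  expect_equal(hydrolysis_probability("forward", 5, tiny_config(1e-3)), 0)
  # strictly increasing in temperature
  temps <- c(0.1, 0.2, 0.4, 0.6)
  vals <- vapply(temps, function(tt)
    hydrolysis_probability("forward", 5, tiny_config(tt)), numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("error probability combines thermal and rate factors and vanishes without mutation", {
  cfg <- tiny_config(temperature = 0.5)
  expect_equal(error_probability(10, cfg), exp(-4))
  expect_equal(error_probability(5, cfg), exp(-4) * sqrt(0.5))
  # non-decreasing in rate
  vals <- vapply(1:10, error_probability, numeric(1), config = cfg)
  expect_true(all(diff(vals) > 0))
  # strictly increasing in temperature
  tvals <- vapply(c(0.1, 0.3, 0.5), function(tt)
    error_probability(5, tiny_config(tt)), numeric(1))
  expect_true(all(diff(tvals) > 0))
  # mutation disabled => exactly zero
  off <- tiny_config(0.5, mutation_enabled = FALSE)
  expect_identical(error_probability(10, off), 0)
  # linear variant for sensitivity checks
  lin <- tiny_config(0.5, rate_factor = "linear")
  expect_equal(error_probability(5, lin), exp(-4) * 0.5)
})

test_that("configuration and rate bounds are enforced", {
  expect_error(sim_config(temperature = 0), "positive")
  expect_error(sim_config(temperature = 0.3, rate_min = 5, rate_max = 2),
               "rate_min")
  expect_error(sim_config(temperature = 0.3, error_tolerance = 1.5), "0, 1")
  cfg <- tiny_config()
  expect_error(hydrolysis_probability("forward", 11, cfg), "rate")
  expect_error(error_probability(0, cfg), "rate")
  expect_error(cull_probability(cfg$capacity + 1, cfg), "capacity")
})

test_that("culling probability is the inverse of remaining capacity, certain at capacity", {
  cfg <- sim_config(temperature = 0.3, capacity = 1000, n_steps = 10,
                    sample_every = 10)
  expect_equal(cull_probability(0, cfg), 1 / 1001)
  expect_equal(cull_probability(1000, cfg), 1)
  probs <- vapply(0:1000, cull_probability, numeric(1), config = cfg)
  expect_true(all(diff(probs) > 0))
})

test_that("inherited rate saturates at the error tolerance and respects the bounds", {
  cfg <- tiny_config(0.4)
  # no errors -> unchanged, no draw consumed
  expect_identical(inherit_rate(7L, 0, cfg), 7L)
  # half-saturation: delta = round(9 * 0.5) = 5 (half away from zero);
  # from the lower bound the sign is forced upward
  expect_identical(inherit_rate(1L, 0.17, cfg), 6L)
  expect_identical(inherit_rate(10L, 0.17, cfg), 5L)
  # at or beyond e_max the magnitude saturates at rate_max - rate_min = 9
  for (E in c(0.34, 0.7, 1.0)) {
    expect_identical(inherit_rate(1L, E, cfg), 10L)
    expect_identical(inherit_rate(10L, E, cfg), 1L)
    # neither sign stays in range from an interior mother: random then clamp
    set.seed(1)
    mids <- replicate(200, inherit_rate(5L, E, cfg))
    expect_true(all(mids %in% c(1L, 10L)))
    expect_true(all(c(1L, 10L) %in% mids))
  }
  # both signs available: drawn roughly uniformly
  set.seed(2)
  both <- replicate(400, inherit_rate(5L, 0.075, cfg))  # delta = 2
  expect_setequal(unique(both), c(3L, 7L))
  expect_gt(mean(both == 7L), 0.35)
  expect_lt(mean(both == 7L), 0.65)
  # mutation disabled: identity for any error fraction
  off <- tiny_config(0.4, mutation_enabled = FALSE)
  expect_identical(inherit_rate(4L, 0.9, off), 4L)
  expect_error(inherit_rate(5L, 1.2, cfg), "error_fraction")
})

test_that("polymerize_step honors the per-direction hydrolysis semantics", {
  # negligible event probabilities: deterministic full-rate addition
  cold <- tiny_config(1e-2, genome_length = 200L)
  org <- new_organism("forward", 5L)
  res <- polymerize_step(org, cold)
  expect_identical(res$added, 5L)
  expect_identical(res$errors, 0L)
  expect_identical(res$organism$copied_count, 5L)
  expect_identical(res$organism$state, "replicating")
  # completion switches to dividing and stops the loop
  short <- tiny_config(1e-2, genome_length = 30L)
  org <- new_organism("forward", 10L, copied_count = 27L)
  res <- polymerize_step(org, short)
  expect_identical(res$added, 3L)
  expect_identical(res$organism$state, "dividing")
  # contract: dividing organisms do not polymerize
  div <- new_organism("forward", 5L)
  div$state <- "dividing"
  expect_error(polymerize_step(div, cold), "dividing")
})

test_that("per-step additions match the binomial and truncated-geometric kinetics", {
  # exact: exhaustive outcome-tree enumeration equals the closed forms
  for (r in 1:6) {
    for (p in c(0.1, 0.35, 0.7)) {
      expect_equal(enumerate_mean_added("forward", r, p), r * (1 - p),
                   tolerance = 1e-12)
      expect_equal(enumerate_mean_added("reverse", r, p),
                   (1 - p) * (1 - (1 - p)^r) / p, tolerance = 1e-12)
    }
  }
  # empirical: mean added per step within 3 SE of the closed form
  cfg <- sim_config(temperature = 0.5, capacity = 10, genome_length = 10000000L,
                    n_steps = 10, sample_every = 10)
  n <- 20000L
  set.seed(11)
  for (d in DIRECTIONS) {
    r <- 6L
    p <- hydrolysis_probability(d, r, cfg)
    org <- new_organism(d, r)
    added <- integer(n)
    for (i in seq_len(n)) {
      res <- polymerize_step(org, cfg)
      org <- res$organism
      added[i] <- res$added
    }
    expected <- if (d == "forward") r * (1 - p)
                else (1 - p) * (1 - (1 - p)^r) / p
    se <- sd(added) / sqrt(n)
    expect_lt(abs(mean(added) - expected), 3 * se)
  }
})

test_that("misincorporation frequency recovers the error probability", {
  cfg <- sim_config(temperature = 0.5, capacity = 10,
                    genome_length = 10000000L, n_steps = 10, sample_every = 10)
  r <- 10L
  p_e <- error_probability(r, cfg)
  set.seed(12)
  org <- new_organism("forward", r)
  additions <- 0L; errors <- 0L
  while (additions < 100000L) {
    res <- polymerize_step(org, cfg)
    org <- res$organism
    additions <- additions + res$added
    errors <- errors + res$errors
  }
  se <- sqrt(p_e * (1 - p_e) / additions)
  expect_lt(abs(errors / additions - p_e), 3 * se)
})

test_that("culling repeats until the first failed draw and matches its exact distribution", {
  cfg <- sim_config(temperature = 0.3, capacity = 4, genome_length = 10,
                    n_steps = 10, sample_every = 10)
  empty <- new_environment(cfg)
  expect_identical(apply_culling(empty, cfg)$removed, 0L)
  make_env <- function(n) {
    env <- new_environment(cfg)
    env$organisms <- replicate(n, new_organism("forward", 5L),
                               simplify = FALSE)
    env
  }
  # at capacity at least one removal is certain
  set.seed(3)
  expect_true(all(replicate(50, apply_culling(make_env(4L), cfg)$removed) >= 1))
  # distribution of removals vs sequential-Bernoulli enumeration (K = 4)
  pmf <- enumerate_cull_pmf(4L, 4L)
  set.seed(4)
  n_trials <- 3000L
  removed <- replicate(n_trials, apply_culling(make_env(4L), cfg)$removed)
  for (m in 0:4) {
    obs <- mean(removed == m)
    se <- sqrt(pmf[m + 1] * (1 - pmf[m + 1]) / n_trials)
    expect_lt(abs(obs - pmf[m + 1]), 3 * se + 1e-12)
  }
  # frequency of >=1 removal at fixed census matches cull_probability
  cfg10 <- sim_config(temperature = 0.3, capacity = 10, genome_length = 10,
                      n_steps = 10, sample_every = 10)
  env3 <- new_environment(cfg10)
  env3$organisms <- replicate(3, new_organism("reverse", 2L), simplify = FALSE)
  p <- cull_probability(3L, cfg10)
  set.seed(5)
  hits <- mean(replicate(4000, apply_culling(env3, cfg10)$removed >= 1))
  expect_lt(abs(hits - p), 3 * sqrt(p * (1 - p) / 4000))
})

test_that("division copies direction, inherits rate, and respects capacity", {
  cfg <- tiny_config(0.4, capacity = 2L)
  env <- new_environment(cfg)
  mother <- new_organism("reverse", 6L, copied_count = 30L)
  mother$state <- "dividing"
  mother$error_count <- 0L
  env$organisms <- list(mother)
  res <- attempt_division(env, 1L, cfg)
  expect_identical(length(res$env$organisms), 2L)
  d <- res$daughter
  expect_identical(d$direction, "reverse")
  expect_identical(d$rate, 6L)  # zero errors -> identical rate
  expect_identical(d$copied_count, 0L)
  expect_identical(d$state, "replicating")
  m <- res$env$organisms[[1L]]
  expect_identical(m$state, "replicating")
  expect_identical(m$copied_count, 0L)
  expect_identical(m$rate, 6L)
})

test_that("division at capacity leaves the mother dividing", {
  cfg <- tiny_config(0.4, capacity = 1L)
  env <- new_environment(cfg)
  mother <- new_organism("forward", 3L, copied_count = 30L)
  mother$state <- "dividing"
  env$organisms <- list(mother)
  res <- attempt_division(env, 1L, cfg)
  expect_null(res$daughter)
  expect_identical(res$env$organisms[[1L]]$state, "dividing")
  expect_identical(length(res$env$organisms), 1L)
  # contract: replicating organisms do not divide
  env$organisms[[1L]]$state <- "replicating"
  expect_error(attempt_division(env, 1L, cfg), "replicating")
})

test_that("a lone fast organism completes its genome in L/rate steps and divides next step", {
  # capacity far above the census so culling is a negligible perturbation
  cfg <- sim_config(temperature = 1e-2, capacity = 100000L,
                    genome_length = 1000, n_steps = 10, sample_every = 10)
  env <- new_environment(cfg)
  env$organisms <- list(new_organism("forward", 10L, copied_count = 0L))
  set.seed(6)
  for (t in 1:99) env <- advance_time_step(env, cfg)$env
  expect_identical(env$organisms[[1L]]$state, "replicating")
  env <- advance_time_step(env, cfg)$env   # step 100: completion
  expect_identical(env$organisms[[1L]]$state, "dividing")
  expect_identical(length(env$organisms), 1L)
  res <- advance_time_step(env, cfg)       # step 101: division
  expect_identical(length(res$env$organisms), 2L)
  expect_identical(nrow(res$births), 1L)
})

test_that("state and bound invariants hold along a stochastic trajectory", {
  cfg <- sim_config(temperature = 0.5, capacity = 15, genome_length = 20,
                    n_steps = 10, sample_every = 10, master_seed = 3)
  plan <- seeding_plan(rep(DIRECTIONS, each = 3), c(1, 5, 10, 1, 5, 10), 2)
  set.seed(cfg$master_seed)
  env <- seed_population(plan, cfg)
  for (t in 1:150) {
    env <- advance_time_step(env, cfg)$env
    expect_lte(length(env$organisms), cfg$capacity)
    for (o in env$organisms) {
      expect_true(o$rate >= cfg$rate_min && o$rate <= cfg$rate_max)
      expect_true(o$copied_count >= 0L &&
                  o$copied_count <= cfg$genome_length)
      expect_true(o$error_count <= o$copied_count)
      expect_identical(o$state == "dividing",
                       o$copied_count == cfg$genome_length)
    }
  }
})
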