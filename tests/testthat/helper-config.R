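# small configurations reused across tests
tiny_config <- function(temperature = 0.4, capacity = 25L,
                        genome_length = 30L, n_steps = 100L,
                        sample_every = 10L, n_runs = 2L,
                        master_seed = 7L, ...) {
  sim_config(temperature = temperature, capacity = capacity,
             genome_length = genome_length, n_steps = n_steps,
             sample_every = sample_every, n_runs = n_runs,
             master_seed = master_seed, ...)
}

# exact expected additions per step from the 2^r outcome tree (forward) or
# the halt-at-first-hydrolysis tree (reverse); independent of the closed
# forms asserted in the tests
enumerate_mean_added <- function(direction, rate, p) {
  if (direction == "forward") {
    total <- 0
    for (bits in 0:(2^rate - 1)) {
      hydro <- sum(bitwAnd(bits, 2^(0:(rate - 1))) > 0)
      prob <- p^hydro * (1 - p)^(rate - hydro)
      total <- total + prob * (rate - hydro)
    }
    total
  } else {
    # k additions then a hydrolysis halt (k < rate), or a full run of `rate`
    total <- 0
    for (k in 0:(rate - 1)) total <- total + ((1 - p)^k * p) * k
    total + (1 - p)^rate * rate
  }
}

# exact distribution of the number of removals in one culling pass starting
# from census n (capacity K, offset eps): sequential Bernoulli enumeration
enumerate_cull_pmf <- function(n, K, eps = 1) {
  pmf <- numeric(n + 1L)  # P(0 removals) ... P(n removals)
  reach <- 1
  for (m in 0:n) {
    cur <- n - m
    if (cur == 0L) { pmf[m + 1L] <- reach; break }
    p <- min(1, 1 / (K - cur + eps))
    pmf[m + 1L] <- reach * (1 - p)
    reach <- reach * p
  }
  pmf
}
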