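# small random networks and session-cached fixtures used across test files

rand_net <- function(n, seed, h_sd = 0.3, J_sd = 0.3, beta = 1) {
  set.seed(seed)
  J <- matrix(rnorm(n * n, 0, J_sd), n)
  J <- (J + t(J)) / 2
  diag(J) <- 0
  ising_network(n, h = rnorm(n, 0, h_sd), J = J, beta = beta)
}

# expensive shared fixtures, built once per test session
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# the critical-lattice correlation reservoir at study scale
study_pool <- function() {
  cached("study_pool", {
    lat <- build_critical_lattice(20)
    harvest_pool(lat, n_sweeps = 1e5, burn_in = 1e4, seed = 20260930)
  })
}

# isolated networks of increasing size trained on the study pool
# (300 updates each), with their sampled heat-capacity curves over the
# 21-point log grid; three replicate networks per size
trained_size_sweeps <- function() {
  cached("trained_size_sweeps", {
    pool <- study_pool()
    set.seed(20260902)
    lapply(c(`8` = 8, `16` = 16, `32` = 32), function(N) {
      replicate(3, simplify = FALSE, {
        fit <- train_isolated(ising_network(N), pool,
                              learning_config(n_updates = 300))
        sw <- sweep_isolated(fit$net, beta_grid(21), n_sweeps = 1e5,
                             burn_in = 5e3)
        list(peak_beta = peak_location(sw$table$beta,
                                       sw$table$heat_capacity),
             peak_C = max(sw$table$heat_capacity))
      })
    })
  })
}

# a Mountain Car agent with 16 hidden units trained on the study pool
# (full training schedule: 1000 trials x 5000 sweeps)
study_agent <- function() {
  cached("study_agent", {
    set.seed(20260901)
    train_embodied(embodied_network(16), "mountain_car", study_pool(),
                   learning_config(n_updates = 1000, trial_steps = 5000))
  })
}

sech2 <- function(x) 1 / cosh(x)^2
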