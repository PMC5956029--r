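#' Learning configuration
#'
#' @param mu positive learning rate of the inverse-Ising gradient rule
#'   (default 0.01).
#' @param n_updates number of gradient applications (isolated training) or
#'   trials (embodied training).
#' @param samples_per_update sweeps used to estimate moments per update;
#'   `NULL` means the default 1000 N for isolated training and the trial
#'   length for embodied training.
#' @param trial_steps sweeps per embodied trial (default 5000).
#' @param reset_every sweeps between environment/network-state resets during
#'   embodied training and sweeps (default 5e4).
#' @return a `learning_config` list.
#' @export
learning_config <- function(mu = 0.01, n_updates = 1000,
                            samples_per_update = NULL, trial_steps = 5000,
                            reset_every = 5e4) {
  stopifnot(mu > 0, n_updates >= 1, trial_steps >= 1, reset_every >= 1)
  structure(list(mu = mu, n_updates = as.integer(n_updates),
                 samples_per_update = samples_per_update,
                 trial_steps = as.integer(trial_steps),
                 reset_every = as.integer(reset_every)),
            class = "learning_config")
}

#' Rank-align reference correlations to measured correlations
#'
#' The k-th largest reference value is assigned to the synapse whose measured
#' correlation is k-th largest, so the rule constrains only the *distribution*
#' of a neuron's correlations, not which synapse carries which value. Ties in
#' the measured values are broken by first synapse index (stable order).
#'
#' @param measured_c numeric vector of measured correlations for one neuron's
#'   synapses.
#' @param reference_c numeric vector of reference values (same length).
#' @return a permutation of `reference_c`, aligned to `measured_c`.
#' @examples
#' rank_align_targets(c(0.9, 0.1, 0.5), c(0.2, 0.8, 0.4))  # 0.8 0.2 0.4
#' @export
rank_align_targets <- function(measured_c, reference_c) {
  if (length(measured_c) != length(reference_c))
    stop("measured and reference vectors must have equal length")
  ord <- order(measured_c, decreasing = TRUE)  # stable: ties by first index
  aligned <- numeric(length(reference_c))
  aligned[ord] <- sort(reference_c, decreasing = TRUE)
  aligned
}

# Per-unit rank alignment, returned as a full N x N matrix A with
# A[i, j] = the reference value unit i currently assigns to synapse (i, j).
align_reference_targets <- function(targets, c_measured) {
  mask <- targets$mask
  n <- nrow(mask)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    partners <- which(mask[i, ])
    if (!length(partners)) next
    A[i, partners] <- rank_align_targets(c_measured[i, partners],
                                         targets$c_star[[i]])
  }
  A
}

#' One inverse-Ising gradient step
#'
#' Boltzmann-learning update towards the reference moments:
#' \deqn{h_i \leftarrow h_i + \mu (m^{*}_i - m^{m}_i), \qquad
#'       J_{ij} \leftarrow J_{ij} + \mu (c^{*}_{ij} - c^{m}_{ij}).}
#' Both endpoints of a pair hold reference values, so every allowed pair
#' receives the two neurons' contributions, applied symmetrically; masked
#' pairs and the diagonal stay zero. Sensor biases are external inputs and
#' are never updated (their `m_star` is `NA`).
#'
#' @param net an `ising_network`.
#' @param targets a `reference_targets` object; its per-neuron `c_star`
#'   vectors are taken in partner order as passed (use
#'   [rank_align_targets()] upstream for the sorting rule).
#' @param measured list with `m` and `c` as returned by [sample_moments()]
#'   or [exact_moments()].
#' @param config a `learning_config` (only `mu` is used).
#' @return the updated network.
#' @export
gradient_step <- function(net, targets, measured, config = learning_config()) {
  mask <- net$mask
  n <- net$n_units
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    partners <- which(mask[i, ])
    if (length(partners) != length(targets$c_star[[i]]))
      stop("targets do not match the network's allowed couplings")
    A[i, partners] <- targets$c_star[[i]]
  }
  dJ <- config$mu * ((A - measured$c) + t(A - measured$c))
  dJ[!mask] <- 0
  net$J <- net$J + dJ
  learnable <- !is.na(targets$m_star)
  net$h[learnable] <- net$h[learnable] +
    config$mu * (targets$m_star[learnable] - measured$m[learnable])
  validate_ising_network(net)
}

# internal: one full update = measure, rank-align, gradient step
learning_update <- function(net, targets, config, exact, n_sweeps, thin = 1) {
  measured <- if (exact) exact_moments(net)
  else sample_moments(net, n_sweeps = n_sweeps, thin = thin)
  if (!exact) net$state <- measured$state  # chain persists across updates
  aligned <- targets
  aligned$c_star <- local({
    A <- align_reference_targets(targets, measured$c)
    lapply(seq_len(net$n_units), function(i) A[i, which(targets$mask[i, ])])
  })
  net <- gradient_step(net, aligned, measured, config)
  err_c <- abs(align_reference_targets(targets, measured$c) -
                 measured$c)[targets$mask]
  learnable <- !is.na(targets$m_star)
  err_m <- abs(measured$m[learnable])
  list(net = net,
       trace = data.frame(max_err_c = max(err_c), mean_err_c = mean(err_c),
                          max_err_m = if (any(learnable)) max(err_m) else NA_real_,
                          norm_J = sqrt(mean(net$J[net$mask]^2)),
                          norm_h = sqrt(mean(net$h^2))))
}

#' Train an isolated network on pool-sampled correlations
#'
#' Repeats `n_updates` cycles of: estimate the moments with Glauber dynamics
#' (`samples_per_update` sweeps, default 1000 N, chain persisting across
#' updates), rank-align the reference correlations to the measured ones, and
#' apply [gradient_step()]. The run does not wait for convergence; the aim is
#' to capture the reference distribution of correlations, after which the
#' network's heat capacity peaks near the operating point \eqn{\beta = 1}.
#'
#' @param net a fully connected `ising_network`, typically with zero initial
#'   `h` and `J`.
#' @param pool a `correlation_pool` to draw reference targets from (ignored
#'   if `targets` is given).
#' @param config a `learning_config`.
#' @param targets optional pre-sampled `reference_targets`.
#' @param exact use exact enumeration instead of sampling for the moments
#'   (small N only); the deterministic gradient-descent oracle.
#' @param seed optional integer seed.
#' @return list with the trained `net`, a per-update `trace` data frame and
#'   the `targets` used.
#' @export
train_isolated <- function(net, pool = NULL, config = learning_config(),
                           targets = NULL, exact = FALSE, seed = NULL) {
  validate_ising_network(net)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(targets)) {
    if (is.null(pool)) stop("either a pool or targets must be supplied")
    targets <- sample_reference_targets(pool, net$mask, net$roles)
  }
  n_sweeps <- config$samples_per_update
  if (is.null(n_sweeps)) n_sweeps <- 1000L * net$n_units
  trace <- vector("list", config$n_updates)
  for (u in seq_len(config$n_updates)) {
    step <- learning_update(net, targets, config, exact, n_sweeps)
    net <- step$net
    trace[[u]] <- step$trace
  }
  trace <- do.call(rbind, trace)
  trace$update <- seq_len(nrow(trace))
  list(net = net, trace = trace, targets = targets)
}

#' Train an embodied agent
#'
#' The network is coupled to the Mountain Car or Acrobot in closed loop:
#' each simulation step writes the encoded observation into the sensor
#' fields, performs one sequential Glauber sweep, decodes the motor units
#' into an action and advances the environment. Moments are time averages
#' over each trial's sweeps; the rank-aligned gradient step is applied at
#' the end of every trial; environment and network state are re-randomised
#' every `reset_every` sweeps. The agent has no task objective -- learning
#' only maintains the reference correlation distribution.
#'
#' @param net an embodied `ising_network` (see [embodied_network()]),
#'   typically with zero initial parameters.
#' @param env `"mountain_car"` or `"acrobot"`.
#' @param pool a `correlation_pool` (ignored if `targets` given).
#' @param config a `learning_config`; `n_updates` trials of `trial_steps`
#'   sweeps.
#' @param targets optional pre-sampled `reference_targets`.
#' @param mass Acrobot link mass (hard-task setting 1.75).
#' @param dt Acrobot integrator step.
#' @param seed optional integer seed.
#' @return list with the trained `net`, per-trial `trace` and `targets`.
#' @export
train_embodied <- function(net, env = c("mountain_car", "acrobot"),
                           pool = NULL, config = learning_config(),
                           targets = NULL, mass = 1.75, dt = 0.2,
                           seed = NULL) {
  env <- match.arg(env)
  validate_ising_network(net)
  if (!any(net$roles == "sensor")) stop("network has no sensor units")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(targets)) {
    if (is.null(pool)) stop("either a pool or targets must be supplied")
    targets <- sample_reference_targets(pool, net$mask, net$roles)
  }
  env_kind <- match(env, c("mountain_car", "acrobot")) - 1L
  roles_int <- roles_to_int(net$roles)
  env_state <- env_init(env)
  sweeps_done <- 0L
  trace <- vector("list", config$n_updates)
  for (trial in seq_len(config$n_updates)) {
    if (sweeps_done %% config$reset_every == 0L) {
      env_state <- env_init(env)
      net$state <- sample(c(-1, 1), net$n_units, replace = TRUE)
    }
    tr <- cpp_run_trial(net$h, net$J, net$beta, net$state, roles_int,
                        env_kind, env_state, config$trial_steps, mass, dt,
                        TRUE, integer(0), FALSE)
    if (!all(is.finite(tr$env_state))) stop("environment diverged")
    net$state <- as.numeric(tr$state)
    env_state <- as.numeric(tr$env_state)
    measured <- list(m = as.numeric(tr$m), c = tr$c)
    aligned <- targets
    A <- align_reference_targets(targets, measured$c)
    aligned$c_star <- lapply(seq_len(net$n_units),
                             function(i) A[i, which(targets$mask[i, ])])
    net <- gradient_step(net, aligned, measured, config)
    err_c <- abs(A - measured$c)[targets$mask]
    learnable <- !is.na(targets$m_star)
    trace[[trial]] <- data.frame(
      trial = trial, max_err_c = max(err_c), mean_err_c = mean(err_c),
      max_err_m = max(abs(measured$m[learnable])),
      mean_height = tr$mean_height)
    sweeps_done <- sweeps_done + config$trial_steps
  }
  list(net = net, trace = do.call(rbind, trace), targets = targets)
}
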