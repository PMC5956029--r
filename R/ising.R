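#' Construct an Ising network (Boltzmann machine)
#'
#' An Ising network is a set of `n_units` binary units \eqn{s_i \in \{-1,+1\}}
#' with local biases \eqn{h_i} and symmetric pairwise couplings \eqn{J_{ij}}
#' (\eqn{J_{ii} = 0}), operating at inverse temperature \eqn{\beta}. Units can
#' optionally be assigned roles (`"sensor"`, `"motor"`, `"hidden"`) for
#' embodied use; the coupling `mask` records which pairs are allowed to carry
#' a nonzero coupling.
#'
#' @param n_units number of units N.
#' @param h numeric bias vector (recycled if scalar). Default 0.
#' @param J symmetric coupling matrix with zero diagonal, or `NULL` for all
#'   zeros.
#' @param mask logical matrix of allowed couplings, or `NULL`. Defaults to
#'   all off-diagonal pairs if no roles are given, and to the
#'   sensor/motor/hidden architecture constraint otherwise (sensor and motor
#'   units couple only to hidden units).
#' @param beta positive inverse temperature. The learning rule operates at
#'   \eqn{\beta = 1}; any other choice is equivalent to rescaling `h` and `J`.
#' @param state spin vector in \{-1, +1\}, or `NULL` for a random state drawn
#'   with the current RNG.
#' @param roles character vector of unit roles; default all `"hidden"`.
#' @return an object of class `ising_network`.
#' @examples
#' net <- ising_network(3, h = c(0.5, 0, -0.5))
#' ising_energy(net, c(1, 1, -1))
#' @export
ising_network <- function(n_units, h = 0, J = NULL, mask = NULL, beta = 1,
                          state = NULL, roles = NULL) {
  stopifnot(n_units >= 1, beta > 0)
  n <- as.integer(n_units)
  h <- rep_len(as.numeric(h), n)
  if (is.null(roles)) roles <- rep("hidden", n)
  stopifnot(length(roles) == n)
  if (is.null(mask)) mask <- architecture_mask(roles)
  mask <- mask & !diag(TRUE, n)
  if (is.null(J)) J <- matrix(0, n, n)
  if (is.null(state)) state <- sample(c(-1, 1), n, replace = TRUE)
  net <- structure(
    list(n_units = n, h = h, J = J, mask = mask, beta = beta,
         state = as.numeric(state), roles = roles),
    class = "ising_network")
  validate_ising_network(net)
}

#' Validate an Ising network's invariants
#'
#' Checks symmetry and zero diagonal of `J`, that masked-out couplings are
#' zero, and that all spins are exactly +1 or -1.
#'
#' @param net an `ising_network`.
#' @return `net`, invisibly usable, after passing all checks.
#' @export
validate_ising_network <- function(net) {
  stopifnot(inherits(net, "ising_network"))
  n <- net$n_units
  if (length(net$h) != n || !all(dim(net$J) == c(n, n)))
    stop("h or J dimensions do not match n_units")
  if (!isTRUE(all.equal(net$J, t(net$J), tolerance = 0)))
    stop("J must be exactly symmetric")
  if (any(diag(net$J) != 0)) stop("J must have zero diagonal")
  if (any(net$J[!net$mask & !diag(TRUE, n)] != 0))
    stop("J must be zero on masked-out pairs")
  if (!all(net$state %in% c(-1, 1))) stop("state entries must be +1 or -1")
  if (!is.finite(net$beta) || net$beta <= 0) stop("beta must be positive")
  net
}

#' @export
print.ising_network <- function(x, ...) {
  cat(sprintf("Ising network: N = %d, beta = %g\n", x$n_units, x$beta))
  tab <- table(factor(x$roles, levels = names(role_codes)))
  if (any(tab[c("sensor", "motor")] > 0))
    cat(sprintf("  roles: %d sensor, %d motor, %d hidden\n",
                tab[["sensor"]], tab[["motor"]], tab[["hidden"]]))
  cat(sprintf("  couplings: %d allowed pairs, max|J| = %.4g, max|h| = %.4g\n",
              sum(x$mask[upper.tri(x$mask)]), max(abs(x$J)), max(abs(x$h))))
  invisible(x)
}

#' Glauber activation probability
#'
#' Probability that a unit takes value `candidate_spin` given its effective
#' field \eqn{H_i = h_i + \sum_j J_{ij} s_j}:
#' \deqn{P(s_i) = [1 + e^{-2\beta H_i s_i}]^{-1}.}
#' The probabilities of the two candidate spins sum to one.
#'
#' @param effective_field finite numeric effective field \eqn{H_i}.
#' @param candidate_spin +1 or -1.
#' @param beta positive inverse temperature.
#' @return probability in \[0, 1\].
#' @examples
#' glauber_probability(1, 1, beta = 1)  # 1 / (1 + exp(-2))
#' @export
glauber_probability <- function(effective_field, candidate_spin, beta = 1) {
  if (!all(is.finite(effective_field))) stop("effective field must be finite")
  stopifnot(all(candidate_spin %in% c(-1, 1)), beta > 0)
  1 / (1 + exp(-2 * beta * effective_field * candidate_spin))
}

#' Run sequential Glauber sweeps
#'
#' One sweep updates every unit exactly once, in a freshly drawn random
#' permutation, each through [glauber_probability()] using the instantaneous
#' state of the other units. One sweep is the package's unit of simulation
#' time ("one simulation step").
#'
#' @param net an `ising_network`.
#' @param n_sweeps number of sweeps to run.
#' @param seed optional integer; if given, `set.seed(seed)` is called first.
#' @return the network with its `state` advanced.
#' @export
sequential_sweep <- function(net, n_sweeps = 1, seed = NULL) {
  validate_ising_network(net)
  if (!is.null(seed)) set.seed(seed)
  net$state <- as.numeric(cpp_sweep(net$h, net$J, net$beta, net$state,
                                    as.integer(n_sweeps)))
  net
}

#' Ising energy of a state
#'
#' \deqn{E(s) = -\sum_i h_i s_i - \sum_{i<j} J_{ij} s_i s_j,}
#' each unordered pair counted once.
#'
#' @param net an `ising_network`.
#' @param state spin vector; defaults to the network's current state.
#' @return the energy, a single number.
#' @export
ising_energy <- function(net, state = net$state) {
  if (length(state) != net$n_units) stop("state length must equal n_units")
  if (!all(state %in% c(-1, 1))) stop("state entries must be +1 or -1")
  -sum(net$h * state) - 0.5 * sum(state * (net$J %*% state))
}

# enumeration refuses above this size rather than silently truncating
.enumeration_cap <- 20L

check_enumeration_cap <- function(n, cap = .enumeration_cap) {
  if (n > cap)
    stop(sprintf("exact enumeration refused for N = %d (cap %d states = 2^%d)",
                 n, cap, cap))
}

#' Exact Boltzmann distribution over all states
#'
#' Enumerates all \eqn{2^N} states and returns
#' \eqn{P(s) \propto e^{-\beta E(s)}}. State `k` (1-based position in the
#' returned vector) has unit `i` equal to +1 iff bit `i - 1` of `k - 1` is
#' set; [spin_states()] materialises this order.
#'
#' @param net an `ising_network` with at most `cap` units.
#' @param cap enumeration cap; networks above it are refused.
#' @return numeric vector of probabilities summing to one, with the state
#'   energies attached as attribute `"energy"`.
#' @export
exact_distribution <- function(net, cap = .enumeration_cap) {
  validate_ising_network(net)
  check_enumeration_cap(net$n_units, cap)
  en <- cpp_enumerate(net$h, net$J, net$beta)
  structure(as.numeric(en$prob), energy = as.numeric(en$energy))
}

#' Enumerate spin states in the canonical order
#'
#' @param n number of units (small).
#' @return a `2^n x n` matrix of -1/+1 rows, in the order used by
#'   [exact_distribution()].
#' @export
spin_states <- function(n) {
  stopifnot(n <= 16)
  k <- 0:(2^n - 1)
  sapply(seq_len(n), function(i) ifelse(bitwAnd(k, bitwShiftL(1L, i - 1L)) > 0, 1, -1))
}

#' Exact moments under the equilibrium distribution
#'
#' @param net an enumerable `ising_network`.
#' @param cap enumeration cap.
#' @return list with per-unit means `m` and the pair second-moment matrix `c`
#'   (\eqn{c_{ij} = \langle s_i s_j\rangle}, diagonal exactly 1).
#' @export
exact_moments <- function(net, cap = .enumeration_cap) {
  validate_ising_network(net)
  check_enumeration_cap(net$n_units, cap)
  mom <- cpp_exact_moments(net$h, net$J, net$beta)
  list(m = as.numeric(mom$m), c = mom$c)
}

#' Exact entropy (nats) of the equilibrium distribution
#'
#' @inheritParams exact_moments
#' @return entropy \eqn{H = -\sum_s P(s) \log P(s)} in nats.
#' @export
exact_entropy <- function(net, cap = .enumeration_cap) {
  p <- exact_distribution(net, cap)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Sampled moments from Glauber dynamics
#'
#' Time averages of \eqn{s_i} and \eqn{s_i s_j} over post-burn-in sweeps.
#' The chain continues from the network's current state, so repeated calls
#' form one persistent chain.
#'
#' @param net an `ising_network`.
#' @param n_sweeps number of recorded sweeps (>= 1).
#' @param burn_in sweeps discarded before recording.
#' @param thin record every `thin`-th sweep.
#' @param seed optional integer seed.
#' @return list with `m`, `c` (diagonal exactly 1), the final `state` (for
#'   chain persistence) and `n_samples`.
#' @export
sample_moments <- function(net, n_sweeps, burn_in = 0, thin = 1, seed = NULL) {
  validate_ising_network(net)
  stopifnot(n_sweeps >= 1)
  if (!is.null(seed)) set.seed(seed)
  out <- cpp_sample_moments(net$h, net$J, net$beta, net$state,
                            as.integer(n_sweeps), as.integer(burn_in),
                            as.integer(thin))
  list(m = as.numeric(out$m), c = out$c, state = as.numeric(out$state),
       n_samples = out$n_samples)
}

#' Heat capacity of an Ising network
#'
#' \deqn{C(\beta) = \beta^2 (\langle E^2\rangle - \langle E\rangle^2),}
#' the variance of the energy under the equilibrium distribution, which also
#' equals \eqn{-\beta\,\partial H/\partial\beta} with \eqn{H} the entropy in
#' nats. `mode = "exact"` enumerates (small N only); `mode = "sampled"`
#' estimates the energy variance from a Glauber run.
#'
#' @param net an `ising_network`.
#' @param mode `"exact"` or `"sampled"`.
#' @param n_sweeps recorded sweeps in sampled mode (must be >= 100).
#' @param burn_in burn-in sweeps in sampled mode.
#' @param seed optional integer seed (sampled mode).
#' @return non-negative heat capacity.
#' @export
heat_capacity <- function(net, mode = c("exact", "sampled"), n_sweeps = 1e4,
                          burn_in = 1000, seed = NULL) {
  mode <- match.arg(mode)
  validate_ising_network(net)
  if (mode == "exact") {
    check_enumeration_cap(net$n_units)
    p <- exact_distribution(net)
    e <- attr(p, "energy")
    return(net$beta^2 * (sum(p * e^2) - sum(p * e)^2))
  }
  if (n_sweeps < 100)
    stop("sampled heat capacity needs n_sweeps >= 100 to estimate a variance")
  if (!is.null(seed)) set.seed(seed)
  st <- cpp_sample_stats(net$h, net$J, net$beta, net$state,
                         as.integer(n_sweeps), as.integer(burn_in),
                         integer(0), 1L)
  net$beta^2 * st$var_energy
}

#' Inverse-temperature sweep of an isolated network
#'
#' For each value of `betas` the network parameters are rescaled
#' (\eqn{h \leftarrow \beta h}, \eqn{J \leftarrow \beta J}, equivalently
#' \eqn{\beta} enters the Glauber probability directly), the chain is
#' restarted from a random state and burned in, and the energy statistics
#' (and optionally a state histogram over a unit subset) are sampled.
#'
#' @param net an `ising_network` (its own `beta` is ignored; the grid is
#'   absolute).
#' @param betas inverse-temperature grid, e.g. [beta_grid()].
#' @param n_sweeps recorded sweeps per beta.
#' @param burn_in burn-in sweeps per beta.
#' @param subset integer unit indices to histogram (<= 24), or `NULL`.
#' @param thin record every `thin`-th sweep.
#' @param seed optional integer seed.
#' @return list with a `table` (`beta`, `mean_energy`, `var_energy`,
#'   `heat_capacity`, and `entropy` when a subset is histogrammed) and the
#'   raw `counts` matrix (states x betas).
#' @export
sweep_isolated <- function(net, betas = beta_grid(21), n_sweeps = 1e4,
                           burn_in = 1000, subset = NULL, thin = 1,
                           seed = NULL) {
  validate_ising_network(net)
  if (!is.null(seed)) set.seed(seed)
  subset0 <- if (is.null(subset)) integer(0) else as.integer(subset) - 1L
  if (length(subset0) > 24) stop("histogram subsets are limited to 24 units")
  out <- cpp_beta_sweep_isolated(net$h, net$J, as.numeric(betas),
                                 as.integer(n_sweeps), as.integer(burn_in),
                                 subset0, as.integer(thin))
  tab <- data.frame(beta = as.numeric(betas),
                    mean_energy = out$mean_energy,
                    var_energy = out$var_energy,
                    heat_capacity = out$heat_capacity)
  if (length(subset0) > 0)
    tab$entropy <- apply(out$counts, 2, entropy_from_counts)
  list(table = tab, counts = out$counts)
}
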