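#' Logarithmic inverse-temperature grid
#'
#' @param n_points number of grid points (>= 2); the study default is 101.
#' @param lo,hi positive endpoints (defaults 0.1 and 10); both are hit
#'   exactly and consecutive ratios are equal.
#' @return numeric grid of length `n_points`.
#' @export
beta_grid <- function(n_points = 101, lo = 0.1, hi = 10) {
  if (!(n_points >= 2 && lo > 0 && hi > lo)) stop("invalid beta grid bounds")
  g <- exp(seq(log(lo), log(hi), length.out = n_points))
  g[1] <- lo
  g[n_points] <- hi
  g
}

#' Plug-in entropy of an empirical distribution (nats)
#'
#' \eqn{H = -\sum_x \hat P(x)\log \hat P(x)} with zero-count states
#' contributing nothing; no bias correction.
#'
#' @param counts non-negative counts with a positive total.
#' @return entropy in nats.
#' @export
entropy_from_counts <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  total <- sum(counts)
  if (total <= 0) stop("all counts are zero")
  p <- counts[counts > 0] / total
  -sum(p * log(p))
}

#' Cubic smoothing-spline fit and derivative
#'
#' Fits a cubic smoothing spline whose residual sum of squares is pushed to
#' the `smoothing` budget: the smoothest spline (largest penalty) with
#' \eqn{\sum_i (y_i - f(x_i))^2 \le} `smoothing` is selected, mirroring the
#' residual-based smoothing condition conventional for B-spline fitting of
#' entropy curves. The derivative is evaluated analytically from the fitted
#' spline.
#'
#' @param x_grid numeric grid (>= 8 points).
#' @param y_values values on the grid.
#' @param smoothing non-negative residual budget (study value 1).
#' @return list with `x`, the `fitted` values and the first `deriv`ative on
#'   the grid.
#' @export
spline_derivative <- function(x_grid, y_values, smoothing = 1) {
  if (length(x_grid) < 8) stop("spline fit needs at least 8 grid points")
  stopifnot(length(y_values) == length(x_grid), smoothing >= 0)
  fit_at <- function(spar) {
    stats::smooth.spline(x_grid, y_values, spar = spar, all.knots = TRUE,
                         keep.data = FALSE)
  }
  rss_at <- function(spar) {
    f <- fit_at(spar)
    sum((y_values - predict(f, x_grid)$y)^2)
  }
  # spar = 1.5 is already the linear-fit limit at these problem sizes;
  # beyond it the penalized system becomes ill-conditioned
  lo <- -1.5; hi <- 1.5
  fit <- if (rss_at(hi) <= smoothing) {
    fit_at(hi)         # even the smoothest fit is within budget
  } else if (rss_at(lo) >= smoothing) {
    fit_at(lo)         # budget unattainable; least-smooth fit
  } else {
    spar <- uniroot(function(s) rss_at(s) - smoothing, c(lo, hi),
                    tol = 1e-4)$root
    fit_at(spar)
  }
  list(x = x_grid,
       fitted = predict(fit, x_grid)$y,
       deriv = predict(fit, x_grid, deriv = 1)$y)
}

#' Heat capacity from an entropy curve
#'
#' \eqn{C(\beta) = -\beta\,\partial H/\partial\beta}, evaluated as
#' \eqn{-\partial H/\partial\ln\beta} from a smoothing-spline fit of the
#' entropy against \eqn{\ln\beta} (natural for a logarithmic grid; the
#' residual budget is unchanged by the reparameterisation).
#'
#' @param betas inverse-temperature grid.
#' @param entropies entropies (nats) on the grid.
#' @param smoothing spline residual budget (study value 1).
#' @return heat-capacity values on the grid.
#' @export
heat_capacity_curve <- function(betas, entropies, smoothing = 1) {
  sd <- spline_derivative(log(betas), entropies, smoothing)
  -sd$deriv
}

#' Behavioural susceptibility from a mean-height curve
#'
#' \eqn{\chi_y(\beta) = \beta\,\partial\langle y\rangle/\partial\beta},
#' evaluated as \eqn{\partial\langle y\rangle/\partial\ln\beta} from a
#' smoothing-spline fit. A sharp peak marks a transition between
#' behavioural regimes of the embodied agent.
#'
#' @param betas inverse-temperature grid.
#' @param mean_heights per-beta mean agent heights.
#' @param smoothing spline residual budget.
#' @return susceptibility values on the grid.
#' @export
susceptibility_curve <- function(betas, mean_heights, smoothing = 1) {
  sd <- spline_derivative(log(betas), mean_heights, smoothing)
  sd$deriv
}

#' Zipf rank-probability curve and log-log slope
#'
#' States are ranked by decreasing empirical probability; the slope of
#' \eqn{\log P} against \eqn{\log \mathrm{rank}} is fitted over the top
#' ranks covering 90% of the probability mass. Under Zipf's law
#' (\eqn{P \propto 1/\mathrm{rank}}) the slope is -1, a scaling signature
#' associated with criticality.
#'
#' @param state_counts state occurrence counts (at least 2 nonzero).
#' @return list with `rank`, `prob` (nonzero states, descending) and the
#'   fitted `slope`.
#' @export
zipf_curve <- function(state_counts) {
  counts <- state_counts[state_counts > 0]
  if (length(counts) < 2) stop("need at least 2 distinct observed states")
  p <- sort(counts, decreasing = TRUE) / sum(counts)
  ranks <- seq_along(p)
  k <- which(cumsum(p) >= 0.9)[1]
  k <- max(k, 2L)
  fit <- lm(log(p[1:k]) ~ log(ranks[1:k]))
  list(rank = ranks, prob = p, slope = unname(coef(fit)[2]), n_fit = k)
}

#' Location of a curve's maximum
#'
#' @param x_grid grid values.
#' @param curve finite curve values on the grid.
#' @return the grid point at the maximum; ties resolve to the smallest `x`.
#' @export
peak_location <- function(x_grid, curve) {
  if (!all(is.finite(curve))) stop("curve must be finite")
  x_grid[which.max(curve)]
}

#' Inverse-temperature sweep of an embodied agent
#'
#' For each \eqn{\beta} the agent's parameters are rescaled
#' (\eqn{h \leftarrow \beta h}, \eqn{J \leftarrow \beta J}; the sensor input
#' field is rescaled with them, since \eqn{\beta} multiplies the full
#' effective field in the Glauber probability) and the agent is simulated
#' for `n_sweeps_per_beta` steps, re-randomising the environment and
#' network state every `reset_every` steps. Collects the state histogram of
#' the chosen unit subset, its plug-in entropy and the mean agent height.
#'
#' @param net a (trained) embodied `ising_network`.
#' @param env `"mountain_car"` or `"acrobot"`.
#' @param betas inverse-temperature grid.
#' @param n_sweeps_per_beta simulation steps per grid point.
#' @param reset_every steps between resets.
#' @param subset `"hidden"` or `"sensor"`: which units to histogram. Hidden
#'   subsets above 24 units are refused; sensor units are the sanctioned
#'   fallback for large networks.
#' @param mass,dt Acrobot parameters.
#' @param seed optional integer seed.
#' @return object of class `beta_sweep`: list with a per-beta `table`
#'   (`beta`, `entropy`, `mean_height`), the histogram `counts` matrix and
#'   the subset used.
#' @export
run_sweep <- function(net, env = c("mountain_car", "acrobot"),
                      betas = beta_grid(101), n_sweeps_per_beta = 1e6,
                      reset_every = 5e4, subset = c("hidden", "sensor"),
                      mass = 1.75, dt = 0.2, seed = NULL) {
  env <- match.arg(env)
  subset <- match.arg(subset)
  validate_ising_network(net)
  if (!is.null(seed)) set.seed(seed)
  idx <- which(net$roles == subset)
  if (length(idx) == 0) stop("no units with the requested role")
  if (length(idx) > 24)
    stop("subset too large to histogram (> 24 units); use subset = 'sensor'")
  env_kind <- match(env, c("mountain_car", "acrobot")) - 1L
  roles_int <- roles_to_int(net$roles)
  n_seg <- ceiling(n_sweeps_per_beta / reset_every)
  counts <- matrix(0, 2^length(idx), length(betas))
  mean_height <- numeric(length(betas))
  for (b in seq_along(betas)) {
    hsum <- 0
    done <- 0
    for (seg in seq_len(n_seg)) {
      steps <- min(reset_every, n_sweeps_per_beta - done)
      env_state <- env_init(env)
      state <- sample(c(-1, 1), net$n_units, replace = TRUE)
      tr <- cpp_run_trial(net$h, net$J, betas[b], state, roles_int, env_kind,
                          env_state, as.integer(steps), mass, dt, FALSE,
                          idx - 1L, FALSE)
      counts[, b] <- counts[, b] + tr$counts
      hsum <- hsum + tr$mean_height * steps
      done <- done + steps
    }
    mean_height[b] <- hsum / done
  }
  structure(
    list(table = data.frame(beta = as.numeric(betas),
                            entropy = apply(counts, 2, entropy_from_counts),
                            mean_height = mean_height),
         counts = counts, subset = subset, env = env),
    class = "beta_sweep")
}

#' Criticality diagnostics of a beta sweep
#'
#' Adds the spline-derivative heat capacity and behavioural susceptibility
#' to a sweep table and locates their peaks.
#'
#' @param sweep a `beta_sweep` from [run_sweep()], or any list with a
#'   `table` containing `beta`, `entropy` and optionally `mean_height`.
#' @param smoothing spline residual budget for the entropy curve (study
#'   value 1; entropies span several nats).
#' @param smoothing_height residual budget for the mean-height curve.
#'   Heights live on a \[0, 1\]-ish scale, so the budget must be smaller
#'   than the entropy one or the spline degenerates to a straight line;
#'   the default matches the sampling noise of the height estimates.
#' @return the sweep with `heat_capacity` (and `susceptibility`) columns
#'   added and `peak_beta` / `peak_beta_susceptibility` elements (the
#'   susceptibility peak is located on \eqn{|\chi_y|}).
#' @export
sweep_diagnostics <- function(sweep, smoothing = 1, smoothing_height = 0.01) {
  tab <- sweep$table
  tab$heat_capacity <- heat_capacity_curve(tab$beta, tab$entropy, smoothing)
  sweep$peak_beta <- peak_location(tab$beta, tab$heat_capacity)
  if (!is.null(tab$mean_height)) {
    tab$susceptibility <- susceptibility_curve(tab$beta, tab$mean_height,
                                               smoothing_height)
    sweep$peak_beta_susceptibility <-
      peak_location(tab$beta, abs(tab$susceptibility))
  }
  sweep$table <- tab
  sweep
}
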