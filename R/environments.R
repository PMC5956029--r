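#' Architecture mask from unit roles
#'
#' Sensor and motor units couple only to hidden units; hidden units couple
#' to everything. No sensor-sensor, sensor-motor or motor-motor couplings
#' and no self-couplings.
#'
#' @param roles character vector of `"sensor"`, `"motor"`, `"hidden"`.
#' @return logical allowed-coupling matrix.
#' @export
architecture_mask <- function(roles) {
  hidden <- roles == "hidden"
  mask <- outer(hidden, hidden, "|")
  diag(mask) <- FALSE
  mask
}

#' Embodied architecture specification
#'
#' The embodied controller has N = 6 + `n_hidden` units: 4 sensors (binary
#' encoding of the observed velocity), 2 motors (decoded into the action)
#' and `n_hidden` hidden units.
#'
#' @param n_hidden number of hidden units.
#' @return list with `n_units`, `roles` and the allowed-coupling `mask`,
#'   of class `architecture_spec`.
#' @export
architecture_spec <- function(n_hidden) {
  stopifnot(n_hidden >= 1)
  roles <- c(rep("sensor", 4), rep("motor", 2), rep("hidden", n_hidden))
  structure(list(n_units = length(roles), roles = roles,
                 mask = architecture_mask(roles)),
            class = "architecture_spec")
}

#' Construct an embodied Ising controller
#'
#' @param n_hidden number of hidden units.
#' @param beta inverse temperature (operating point 1).
#' @return an `ising_network` with zero parameters, sensor/motor/hidden
#'   roles and the architecture's coupling mask.
#' @export
embodied_network <- function(n_hidden, beta = 1) {
  arch <- architecture_spec(n_hidden)
  ising_network(arch$n_units, h = 0, beta = beta, roles = arch$roles,
                mask = arch$mask)
}

# fresh start states used for training, evaluation and resets
env_init <- function(env = c("mountain_car", "acrobot")) {
  env <- match.arg(env)
  if (env == "mountain_car") c(x = runif(1, -0.6, -0.4), v = 0)
  else runif(4, -0.1, 0.1)
}

#' Advance the Mountain Car one step
#'
#' Dynamics of the under-powered car on the two-hill track:
#' \eqn{v(t+1) = v(t) + 0.001 a - 0.0025\cos(3x)}, with the hard-task
#' velocity cap \eqn{|v| \le 0.045}, then \eqn{x(t+1) = x(t) + v(t+1)}
#' clamped to \eqn{[-1.5\pi, 0.5\pi]}. The left wall is inelastic (velocity
#' zeroed); reaching the right bound is the success event and is recorded in
#' attribute `"reached"`.
#'
#' @param state numeric `c(x, v)`.
#' @param action -1, 0 or +1.
#' @return the new `c(x, v)` with attribute `"reached"`.
#' @export
mc_step <- function(state, action) {
  stopifnot(action %in% c(-1, 0, 1))
  out <- cpp_mc_step(state[[1]], state[[2]], as.integer(action))
  structure(c(x = out[1], v = out[2]), reached = out[3] > 0)
}

#' Mountain Car track height
#'
#' \eqn{y = 0.55 + 0.45 \sin(3x)}.
#'
#' @param x horizontal position.
#' @return height of the track at `x`.
#' @export
mc_height <- function(x) 0.55 + 0.45 * sin(3 * x)

#' Acrobot equations of motion
#'
#' Time derivatives of \eqn{(\theta_1, \theta_2, \dot\theta_1, \dot\theta_2)}
#' for the standard two-link underactuated pendulum with torque `torque` on
#' the middle joint; constants \eqn{l_1 = l_2 = 1}, \eqn{l_{c1} = l_{c2} =
#' 0.5}, \eqn{I_1 = I_2 = 1}, \eqn{g = 9.8} and link mass `mass` (hard-task
#' setting 1.75).
#'
#' @param state numeric `c(theta1, theta2, dtheta1, dtheta2)`.
#' @param torque -1, 0 or +1.
#' @param mass link mass.
#' @return numeric vector of the four time derivatives.
#' @export
acrobot_derivatives <- function(state, torque, mass = 1.75) {
  stopifnot(torque %in% c(-1, 0, 1))
  as.numeric(cpp_acrobot_deriv(state[[1]], state[[2]], state[[3]], state[[4]],
                               torque, mass))
}

#' Advance the Acrobot one step
#'
#' Classical fourth-order Runge-Kutta step of the equations of motion with
#' constant torque; afterwards angles are wrapped to \eqn{(-\pi, \pi]} and
#' angular velocities clamped to \eqn{\pm 4\pi} (link 1) and \eqn{\pm 9\pi}
#' (link 2), the benchmark's conventional bounds.
#'
#' @inheritParams acrobot_derivatives
#' @param dt integration step (benchmark convention 0.2).
#' @param clamp wrap angles and clamp velocities after the step (disable for
#'   integrator-accuracy checks).
#' @return the new state vector.
#' @export
acrobot_step <- function(state, torque, dt = 0.2, mass = 1.75, clamp = TRUE) {
  stopifnot(torque %in% c(-1, 0, 1), dt > 0)
  out <- as.numeric(cpp_acrobot_step(as.numeric(state), as.integer(torque),
                                     dt, mass, clamp))
  if (!all(is.finite(out))) stop("acrobot integration produced non-finite state")
  out
}

#' Acrobot tip height
#'
#' Vertical position of the tip of the second link,
#' \eqn{y = -\cos\theta_1 - \cos(\theta_1 + \theta_2)}, in \[-2, 2\];
#' the success threshold of the hard task is y > 1.8.
#'
#' @param state numeric `c(theta1, theta2, dtheta1, dtheta2)`.
#' @return tip height.
#' @export
acrobot_tip_height <- function(state) {
  -cos(state[[1]]) - cos(state[[1]] + state[[2]])
}

#' Encode a bounded observation into 4 sensor spins
#'
#' The value is clipped into `bounds` and mapped to one of 16 equal
#' half-open bins; the bin index is written in plain binary, most
#' significant bit first, with bits mapped \{0 -> -1, 1 -> +1\}.
#'
#' @param value observed scalar.
#' @param bounds numeric `c(lo, hi)` with `hi > lo`.
#' @return 4 spins in \{-1, +1\}.
#' @examples
#' encode_sensors(0, c(-1, 1))  # midpoint -> bin 8 -> (+1, -1, -1, -1)
#' @export
encode_sensors <- function(value, bounds) {
  lo <- bounds[[1]]; hi <- bounds[[2]]
  if (!(hi > lo)) stop("degenerate sensor bounds")
  bin <- floor((value - lo) / (hi - lo) * 16)
  bin <- max(0, min(15, bin))
  bits <- bitwAnd(bitwShiftR(as.integer(bin), 3:0), 1L)
  ifelse(bits > 0, 1, -1)
}

#' Decode the motor units into an action
#'
#' Spin agreement: both motors +1 gives +1, both -1 gives -1, disagreement
#' gives 0. With independent fair-coin motors the three actions have
#' probabilities 1/4, 1/2, 1/4.
#'
#' @param motor_spins 2 spins in \{-1, +1\}.
#' @return -1, 0 or +1.
#' @export
decode_action <- function(motor_spins) {
  stopifnot(length(motor_spins) == 2, all(motor_spins %in% c(-1, 1)))
  if (all(motor_spins == 1)) return(1)
  if (all(motor_spins == -1)) return(-1)
  0
}

# observation bounds used for sensor encoding
sensor_bounds <- function(env) {
  if (env == "mountain_car") c(-0.045, 0.045) else c(-4 * pi, 4 * pi)
}

#' One agent-environment step
#'
#' In order: (1) the encoded observation (Mountain Car: car velocity;
#' Acrobot: angular speed of the first link) is written into the sensor
#' biases, \eqn{h_i = I_i}; (2) one sequential Glauber sweep; (3) the motor
#' units are decoded into the action; (4) the environment advances one step.
#'
#' This is the reference single-step implementation; [run_agent()] executes
#' the same loop in compiled code and follows the identical RNG stream.
#'
#' @param net an embodied `ising_network`.
#' @param env `"mountain_car"` or `"acrobot"`.
#' @param env_state environment state vector.
#' @param mass,dt Acrobot parameters.
#' @return list with the updated `net`, `env_state`, the `action` taken and
#'   the resulting `height`.
#' @export
agent_env_step <- function(net, env = c("mountain_car", "acrobot"),
                           env_state, mass = 1.75, dt = 0.2) {
  env <- match.arg(env)
  obs <- if (env == "mountain_car") env_state[[2]] else env_state[[3]]
  sensors <- which(net$roles == "sensor")
  net$h[sensors] <- encode_sensors(obs, sensor_bounds(env))
  net <- sequential_sweep(net, 1)
  action <- decode_action(net$state[net$roles == "motor"])
  if (env == "mountain_car") {
    env_state <- mc_step(env_state, action)
    height <- mc_height(env_state[[1]])
  } else {
    env_state <- acrobot_step(env_state, action, dt = dt, mass = mass)
    height <- acrobot_tip_height(env_state)
  }
  list(net = net, env_state = env_state, action = action, height = height)
}

#' Run an embodied agent for many steps (compiled loop)
#'
#' @param net an embodied `ising_network`.
#' @param env `"mountain_car"` or `"acrobot"`.
#' @param n_steps number of simulation steps (sweeps).
#' @param env_state starting environment state, or `NULL` for a fresh
#'   task-standard start.
#' @param beta inverse temperature applied to the full effective field
#'   (default: the network's).
#' @param collect_moments accumulate trial moments.
#' @param subset integer unit indices to histogram (<= 24), or `NULL`.
#' @param record_heights return the full height trace.
#' @param mass,dt Acrobot parameters.
#' @param seed optional integer seed.
#' @return list with final `state` and `env_state`, `mean_height`,
#'   `success`, and optionally `m`, `c`, `counts`, `heights`.
#' @export
run_agent <- function(net, env = c("mountain_car", "acrobot"), n_steps,
                      env_state = NULL, beta = net$beta,
                      collect_moments = FALSE, subset = NULL,
                      record_heights = FALSE, mass = 1.75, dt = 0.2,
                      seed = NULL) {
  env <- match.arg(env)
  validate_ising_network(net)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(env_state)) env_state <- env_init(env)
  env_kind <- match(env, c("mountain_car", "acrobot")) - 1L
  subset0 <- if (is.null(subset)) integer(0) else as.integer(subset) - 1L
  out <- cpp_run_trial(net$h, net$J, beta, net$state, roles_to_int(net$roles),
                       env_kind, as.numeric(env_state), as.integer(n_steps),
                       mass, dt, collect_moments, subset0, record_heights)
  out$state <- as.numeric(out$state)
  out$env_state <- as.numeric(out$env_state)
  out
}

#' Success rate of randomly parameterised controllers
#'
#' The hard-task baseline: `n_controllers` networks with biases and allowed
#' couplings drawn uniformly from `param_range` are each run once. A
#' Mountain Car run succeeds if the position bound \eqn{0.5\pi} is reached
#' at least once within `n_steps` (default 1000) from a random start in the
#' valley (\eqn{x \in [-0.6, -0.4]}, v = 0); an Acrobot run succeeds if the
#' tip exceeds height 1.8 within `n_steps` (default 5000) from near-rest
#' (angles and speeds uniform in \eqn{[-0.1, 0.1]}).
#'
#' @param env `"mountain_car"` or `"acrobot"`.
#' @param n_controllers number of random controllers.
#' @param param_range numeric `c(lo, hi)` for the uniform parameter draw.
#' @param n_steps steps per run; `NULL` for the task default.
#' @param n_hidden hidden units of each controller (N = 6 + n_hidden;
#'   default a small controller, N = 10).
#' @param mass,dt Acrobot parameters.
#' @param seed optional integer seed.
#' @return the success fraction in \[0, 1\], with the per-controller
#'   outcomes attached as attribute `"successes"`.
#' @export
random_controller_success_rate <- function(env = c("mountain_car", "acrobot"),
                                           n_controllers = 1000,
                                           param_range = c(-2, 2),
                                           n_steps = NULL, n_hidden = 4,
                                           mass = 1.75, dt = 0.2,
                                           seed = NULL) {
  env <- match.arg(env)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n_steps)) n_steps <- if (env == "mountain_car") 1000L else 5000L
  env_kind <- match(env, c("mountain_car", "acrobot")) - 1L
  succ <- cpp_random_controllers(env_kind, as.integer(n_controllers),
                                 as.integer(n_steps), as.integer(n_hidden),
                                 param_range[[1]], param_range[[2]], mass, dt)
  structure(mean(succ), successes = succ)
}
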