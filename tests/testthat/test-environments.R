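test_that("mountain car follows the printed update rule with a hard velocity cap", {
  # valley equilibrium: cos(3 * -pi/6) = 0
  st <- mc_step(c(-pi / 6, 0), 0)
  expect_equal(as.numeric(st), c(-pi / 6, 0), tolerance = 1e-12)
  # direct formula: v' = 0.001 - 0.0025, x' = v'
  st2 <- mc_step(c(0, 0), 1)
  expect_equal(as.numeric(st2), c(-0.0015, -0.0015))
  # the cap binds whatever the action history
  st3 <- c(x = -pi / 2, v = 0.044)
  for (k in 1:200) {
    st3 <- mc_step(st3, sample(c(-1, 0, 1), 1))
    expect_lte(abs(st3[["v"]]), 0.045)
    expect_gte(st3[["x"]], -1.5 * pi)
    expect_lte(st3[["x"]], 0.5 * pi)
  }
  # inelastic left wall
  st4 <- c(x = -1.5 * pi + 0.001, v = -0.045)
  st4 <- mc_step(st4, -1)
  expect_equal(st4[["x"]], -1.5 * pi)
  expect_equal(st4[["v"]], 0)
})

test_that("mountain car track height matches the printed profile", {
  expect_equal(mc_height(pi / 6), 1)
  expect_equal(mc_height(-pi / 6), 0.1)
  expect_equal(mc_height(0), 0.55)
})

test_that("acrobot accelerations match the benchmark equations", {
  # hanging rest is an equilibrium of the unforced system
  expect_equal(acrobot_derivatives(c(0, 0, 0, 0), 0), rep(0, 4),
               tolerance = 1e-14)

  # independent arithmetic from the printed constants, at theta2 = 0, rest:
  m <- 1.75; l1 <- 1; lc1 <- 0.5; lc2 <- 0.5; I1 <- 1; I2 <- 1
  d1 <- m * lc1^2 + m * (l1^2 + lc2^2 + 2 * l1 * lc2) + I1 + I2   # 6.375
  d2 <- m * (lc2^2 + l1 * lc2) + I2                               # 2.3125
  expect_equal(d2, 2.3125)
  denom <- m * lc2^2 + I2 - d2^2 / d1
  # at rest the gravity terms vanish, so the torque response isolates denom
  dd_tau <- acrobot_derivatives(c(0, 0, 0, 0), 1)
  expect_equal(dd_tau[4], 1 / denom, tolerance = 1e-12)
  expect_equal(dd_tau[3], -(d2 / d1) / denom, tolerance = 1e-12)

  # horizontal first link: phi2 = m lc2 g cos(0) = 8.575
  g <- 9.8
  phi2 <- m * lc2 * g
  expect_equal(phi2, 8.575)
  phi1 <- (m * lc1 + m * l1) * g + phi2
  dd_g <- acrobot_derivatives(c(pi / 2, 0, 0, 0), 0)
  expect_equal(dd_g[4], ((d2 / d1) * phi1 - phi2) / denom, tolerance = 1e-12)
  expect_equal(dd_g[3], -(d2 * dd_g[4] + phi1) / d1, tolerance = 1e-12)
})

test_that("acrobot integration is accurate and respects state bounds", {
  # equilibrium is preserved exactly by the integrator
  expect_equal(acrobot_step(c(0, 0, 0, 0), 0), rep(0, 4), tolerance = 1e-14)
  # tip heights
  expect_equal(acrobot_tip_height(c(0, 0, 0, 0)), -2)
  expect_equal(acrobot_tip_height(c(pi, 0, 0, 0)), 2)
  expect_equal(acrobot_tip_height(c(pi, pi, 0, 0)), 0)

  # dt = 0.2 trajectory agrees with a 10x finer reference integration
  s1 <- c(0.05, -0.03, 0.02, 0.01)
  s2 <- s1
  for (i in 1:50) s1 <- acrobot_step(s1, 0, dt = 0.2, clamp = FALSE)
  for (i in 1:500) s2 <- acrobot_step(s2, 0, dt = 0.02, clamp = FALSE)
  expect_lt(abs(acrobot_tip_height(s1) - acrobot_tip_height(s2)), 1e-3)
  expect_lt(max(abs(s1 - s2)), 0.05)

  # driven hard, angles stay wrapped and angular velocities clamped
  set.seed(14)
  st <- c(0.1, 0, 0, 0)
  for (k in 1:300) {
    st <- acrobot_step(st, sample(c(-1, 1), 1))
    expect_true(st[1] > -pi && st[1] <= pi)
    expect_true(st[2] > -pi && st[2] <= pi)
    expect_lte(abs(st[3]), 4 * pi)
    expect_lte(abs(st[4]), 9 * pi)
  }
})

test_that("sensor encoding maps 16 half-open bins to 4 spins, MSB first", {
  expect_equal(encode_sensors(-1, c(-1, 1)), c(-1, -1, -1, -1))
  expect_equal(encode_sensors(1, c(-1, 1)), c(1, 1, 1, 1))
  expect_equal(encode_sensors(0, c(-1, 1)), c(1, -1, -1, -1))     # bin 8
  expect_equal(encode_sensors(1 - 1e-9, c(-1, 1)), c(1, 1, 1, 1)) # bin 15
  # out-of-range values are clipped
  expect_equal(encode_sensors(-5, c(-1, 1)), c(-1, -1, -1, -1))
  # bin index is non-decreasing in the value
  vals <- seq(-1, 1, length.out = 200)
  bins <- vapply(vals, function(v) {
    sum((encode_sensors(v, c(-1, 1)) + 1) / 2 * c(8, 4, 2, 1))
  }, numeric(1))
  expect_true(all(diff(bins) >= 0))
  expect_equal(sort(unique(bins)), 0:15)
  expect_error(encode_sensors(0, c(1, 1)), "degenerate")
})

test_that("action decoding is the symmetric spin-agreement rule", {
  expect_equal(decode_action(c(1, 1)), 1)
  expect_equal(decode_action(c(-1, -1)), -1)
  expect_equal(decode_action(c(1, -1)), 0)
  expect_equal(decode_action(c(-1, 1)), 0)
  expect_error(decode_action(c(0, 1)))
})

test_that("the agent-environment loop writes sensor fields and is deterministic", {
  net <- embodied_network(3)
  set.seed(5)
  net$J[net$mask] <- runif(sum(net$mask), -0.5, 0.5)
  net$J <- (net$J + t(net$J)) / 2
  net$J[!net$mask] <- 0

  # sensor biases equal the encoded observation exactly
  es <- c(-0.5, 0.012)
  st <- agent_env_step(net, "mountain_car", es)
  expect_equal(st$net$h[net$roles == "sensor"],
               encode_sensors(0.012, c(-0.045, 0.045)))

  # the compiled trial runner follows the identical RNG stream as the
  # step-by-step reference implementation, for both environments
  for (env in c("mountain_car", "acrobot")) {
    e0 <- if (env == "mountain_car") c(-0.5, 0.01) else c(0.05, 0.05, -0.02, 0.03)
    set.seed(9)
    hr <- numeric(30)
    nn <- net
    ee <- e0
    for (t in 1:30) {
      s <- agent_env_step(nn, env, ee)
      nn <- s$net; ee <- s$env_state; hr[t] <- s$height
    }
    cc <- run_agent(net, env, 30, env_state = e0, record_heights = TRUE,
                    seed = 9)
    expect_identical(cc$heights, hr)
    cc2 <- run_agent(net, env, 30, env_state = e0, record_heights = TRUE,
                     seed = 9)
    expect_identical(cc$heights, cc2$heights)
    expect_identical(cc$state, cc2$state)
  }
})

test_that("uncoupled motors act as fair coins", {
  net <- embodied_network(2)   # all parameters zero
  out <- run_agent(net, "mountain_car", 8000, env_state = c(-0.5, 0),
                   collect_moments = TRUE, seed = 77)
  motors <- net$roles == "motor"
  expect_true(all(abs(out$m[motors]) < 4 / sqrt(8000)))
  # independent fair motors: P(action +1) = P(-1) = 1/4
  expect_equal(out$c[which(motors)[1], which(motors)[2]], 0,
               tolerance = 4 / sqrt(8000))
})

test_that("random-controller baseline is seeded and bounded; the zero controller fails", {
  r1 <- random_controller_success_rate("mountain_car", n_controllers = 50,
                                       seed = 123)
  r2 <- random_controller_success_rate("mountain_car", n_controllers = 50,
                                       seed = 123)
  expect_identical(as.numeric(r1), as.numeric(r2))
  expect_gte(r1, 0)
  expect_lte(r1, 1)
  # all-zero parameters: motors dither, the car cannot leave the valley
  net <- embodied_network(4)
  out <- run_agent(net, "mountain_car", 1000, env_state = c(-0.5, 0),
                   seed = 31)
  expect_false(out$success)
})
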