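test_that("rank alignment pairs the k-th largest reference with the k-th largest measured", {
  expect_equal(rank_align_targets(c(0.9, 0.1, 0.5), c(0.2, 0.8, 0.4)),
               c(0.8, 0.2, 0.4))
  # already-descending measured with sorted reference: order unchanged
  expect_equal(rank_align_targets(c(0.7, 0.5, 0.2), c(0.9, 0.6, 0.1)),
               c(0.9, 0.6, 0.1))
  # ties broken by first synapse index
  expect_equal(rank_align_targets(c(0.5, 0.5), c(0.3, 0.7)), c(0.7, 0.3))
  expect_error(rank_align_targets(c(1, 2), c(1, 2, 3)), "equal length")

  # property: output is always a permutation, concordant with measured ranks
  set.seed(10)
  for (rep in 1:20) {
    k <- sample(2:12, 1)
    meas <- runif(k)
    ref <- runif(k)
    al <- rank_align_targets(meas, ref)
    expect_equal(sort(al), sort(ref))
    expect_equal(order(meas, decreasing = TRUE),
                 order(al, seq_len(k), decreasing = c(TRUE, FALSE),
                       method = "radix"))
  }
})

make_targets <- function(net, c_star_mat, m_star = NULL) {
  if (is.null(m_star)) m_star <- rep(0, net$n_units)
  structure(list(
    c_star = lapply(seq_len(net$n_units),
                    function(i) c_star_mat[i, which(net$mask[i, ])]),
    m_star = m_star, mask = net$mask, roles = net$roles),
    class = "reference_targets")
}

test_that("gradient step has the measured moments as its fixed point", {
  net <- rand_net(4, seed = 21)
  mom <- exact_moments(net)
  tg <- make_targets(net, mom$c, m_star = mom$m)
  stepped <- gradient_step(net, tg, mom, learning_config(mu = 0.01))
  expect_identical(stepped$J, net$J)
  expect_identical(stepped$h, net$h)
})

test_that("gradient step applies mu (c* - c) per contribution and spares sensors", {
  # one-sided contribution on a single pair: Delta J = mu (0.5 - 0.3) = 0.002
  net <- ising_network(2)
  measured <- list(m = c(0, 0), c = matrix(c(1, 0.3, 0.3, 1), 2))
  cs <- matrix(0, 2, 2)
  cs[1, 2] <- 0.5          # unit 1 wants 0.5
  cs[2, 1] <- 0.3          # unit 2 is already satisfied
  tg <- make_targets(net, cs)
  stepped <- gradient_step(net, tg, measured, learning_config(mu = 0.01))
  expect_equal(stepped$J[1, 2], 0.002, tolerance = 1e-15)
  expect_equal(stepped$J, t(stepped$J))

  # sensor bias is an external input, never learned
  arch <- architecture_spec(2)
  enet <- embodied_network(2)
  enet$h[arch$roles == "sensor"] <- c(1, -1, 1, -1)
  mom <- list(m = rep(0.4, enet$n_units),
              c = diag(enet$n_units) * 0 + 0.2)
  diag(mom$c) <- 1
  tg2 <- sample_reference_targets(fixture_generator("synthetic-pool", 50),
                                  enet$mask, enet$roles, seed = 1)
  stepped2 <- gradient_step(enet, tg2, mom, learning_config(mu = 0.05))
  sensors <- arch$roles == "sensor"
  expect_identical(stepped2$h[sensors], enet$h[sensors])
  expect_false(any(stepped2$h[!sensors] == enet$h[!sensors]))
})

test_that("symmetry, zero diagonal and mask survive arbitrary update sequences", {
  set.seed(33)
  net <- embodied_network(3)
  pool <- fixture_generator("synthetic-pool", 60, seed = 2)
  tg <- sample_reference_targets(pool, net$mask, net$roles, seed = 3)
  for (u in 1:25) {
    mom <- list(m = runif(net$n_units, -1, 1), c = {
      cc <- matrix(runif(net$n_units^2, -1, 1), net$n_units)
      cc <- (cc + t(cc)) / 2
      diag(cc) <- 1
      cc
    })
    net <- gradient_step(net, tg, mom, learning_config(mu = 0.05))
  }
  expect_identical(net$J, t(net$J))
  expect_true(all(diag(net$J) == 0))
  expect_true(all(net$J[!net$mask & !diag(TRUE, net$n_units)] == 0))
})

test_that("exact-gradient learning matches pool targets on a small network", {
  # targets drawn from the critical-lattice reservoir, moments by
  # enumeration: the residual floor is set by the per-pair target spread
  fit <- train_isolated(ising_network(4), study_pool(),
                        learning_config(mu = 0.01, n_updates = 1000),
                        exact = TRUE, seed = 6)
  expect_lt(tail(fit$trace$max_err_c, 1), 0.05)
  # error trace is non-increasing up to learning-rate-scale re-sorting jitter
  d <- diff(fit$trace$max_err_c)
  expect_lte(mean(d > 0.001), 0.01)
})

test_that("exact gradient descent recovers a known network's moments (unique maxent fit)", {
  true_net <- rand_net(5, seed = 9)
  tm <- exact_moments(true_net)
  tg <- make_targets(true_net, tm$c, m_star = tm$m)
  net <- ising_network(5)
  cfg <- learning_config(mu = 0.1)
  for (u in 1:4000) net <- gradient_step(net, tg, exact_moments(net), cfg)
  mom <- exact_moments(net)
  expect_lt(max(abs(mom$m - tm$m)), 1e-3)
  expect_lt(max(abs(mom$c - tm$c)[net$mask]), 1e-3)
  # the maxent solution is unique: parameters are recovered too
  expect_lt(max(abs(net$J - true_net$J)), 1e-3)
  expect_lt(max(abs(net$h - true_net$h)), 1e-3)
})

test_that("sampled isolated training reduces moment error and keeps invariants", {
  pool <- fixture_generator("synthetic-pool", 300, seed = 12)
  fit <- train_isolated(ising_network(8), pool,
                        learning_config(n_updates = 60), seed = 13)
  expect_identical(fit$net$J, t(fit$net$J))
  expect_true(all(diag(fit$net$J) == 0))
  expect_lt(mean(tail(fit$trace$mean_err_c, 10)),
            mean(head(fit$trace$mean_err_c, 5)))
  expect_equal(nrow(fit$trace), 60)
})

test_that("networks trained on the critical pool develop a heat-capacity peak at beta = 1", {
  pool <- study_pool()
  fit <- train_isolated(ising_network(16), pool,
                        learning_config(n_updates = 300), seed = 17)
  sw <- sweep_isolated(fit$net, beta_grid(21), n_sweeps = 3e4, burn_in = 3e3,
                       seed = 18)
  pk <- peak_location(sw$table$beta, sw$table$heat_capacity)
  # within one grid step of the operating temperature
  expect_lte(abs(log10(pk)), 2 / 20 + 1e-9)
})

test_that("embodied training pulls the correlation distribution towards the pool", {
  pool <- fixture_generator("synthetic-pool", 200, seed = 19)
  net <- embodied_network(4)
  fit <- train_embodied(net, "mountain_car", pool,
                        learning_config(n_updates = 120, trial_steps = 1000),
                        seed = 20)
  expect_identical(fit$net$J, t(fit$net$J))
  expect_true(all(fit$net$J[!fit$net$mask] == 0))
  expect_equal(nrow(fit$trace), 120)
  # correlation error shrinks as training proceeds
  expect_lt(mean(tail(fit$trace$mean_err_c, 30)),
            mean(fit$trace$mean_err_c[31:60]))
  # per-trial mean errors stay moderate: the bias update dithers against
  # the magnetised branches the coupled network falls into
  expect_lt(stats::median(fit$trace$max_err_m), 0.3)
  # trained correlations are closer to the reference distribution than the
  # untrained (zero-parameter) agent's
  ks_dist <- function(a, b) suppressWarnings(ks.test(a, b)$statistic)
  out <- run_agent(fit$net, "mountain_car", 2e4, collect_moments = TRUE,
                   seed = 21)
  out0 <- run_agent(net, "mountain_car", 2e4, collect_moments = TRUE,
                    seed = 22)
  mask <- net$mask
  expect_lt(ks_dist(out$c[mask], unlist(fit$targets$c_star)),
            ks_dist(out0$c[mask], unlist(fit$targets$c_star)))
})
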