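test_that("beta grid is logarithmic with exact endpoints", {
  g <- beta_grid(101, 0.1, 10)
  expect_identical(g[1], 0.1)
  expect_identical(g[101], 10)
  expect_equal(g[51], 1, tolerance = 1e-12)
  expect_equal(diff(log(g)), rep(diff(log(g))[1], 100), tolerance = 1e-10)
  expect_error(beta_grid(1), "invalid")
  expect_error(beta_grid(10, -1, 1), "invalid")
})

test_that("plug-in entropy of counts", {
  expect_equal(entropy_from_counts(c(5, 5, 5, 5)), log(4))
  expect_equal(entropy_from_counts(c(0, 7, 0)), 0)
  expect_equal(entropy_from_counts(c(3, 1)),
               -(0.75 * log(0.75) + 0.25 * log(0.25)))
  expect_error(entropy_from_counts(c(0, 0)), "zero")
  expect_error(entropy_from_counts(c(-1, 2)), "non-negative")
})

test_that("smoothing-spline derivative recovers linear and constant trends", {
  x <- seq(0, 1, length.out = 21)
  sd <- spline_derivative(x, 2 + 3 * x, smoothing = 1)
  expect_equal(sd$deriv, rep(3, 21), tolerance = 1e-6)
  sd0 <- spline_derivative(x, rep(1.4, 21), smoothing = 1)
  expect_equal(sd0$deriv, rep(0, 21), tolerance = 1e-6)
  # noisy line: slope recovered within 5% of the least-squares oracle
  set.seed(8)
  y <- 1 + 0.8 * x + rnorm(21, 0, 0.01)
  ls_slope <- unname(coef(lm(y ~ x))[2])
  sdn <- spline_derivative(x, y, smoothing = 21 * 0.01^2)
  expect_equal(mean(sdn$deriv), ls_slope, tolerance = 0.05 * abs(ls_slope))
  expect_error(spline_derivative(x[1:5], y[1:5]), "at least 8")
})

test_that("heat capacity and susceptibility curves obey their closed forms", {
  b <- beta_grid(21)
  # H = -a ln(beta)  =>  C = -beta dH/dbeta = a
  expect_equal(heat_capacity_curve(b, -0.7 * log(b)), rep(0.7, 21),
               tolerance = 1e-6)
  expect_equal(heat_capacity_curve(b, rep(2, 21)), rep(0, 21),
               tolerance = 1e-6)
  # <y> = ln(beta)  =>  chi_y = beta d<y>/dbeta = 1
  expect_equal(susceptibility_curve(b, log(b), smoothing = 1e-8),
               rep(1, 21), tolerance = 1e-5)
  expect_equal(susceptibility_curve(b, rep(0.3, 21)), rep(0, 21),
               tolerance = 1e-6)
})

test_that("sampled-entropy spline heat capacity matches exact enumeration", {
  net <- rand_net(5, seed = 51, h_sd = 0.2, J_sd = 0.5)
  betas <- beta_grid(21, 0.1, 10)
  sw <- sweep_isolated(net, betas, n_sweeps = 5e4, burn_in = 5e3,
                       subset = 1:5, seed = 52)
  C_spline <- heat_capacity_curve(betas, sw$table$entropy,
                                  smoothing = 21 * 0.003^2)
  C_exact <- vapply(betas, function(b) {
    heat_capacity(ising_network(5, net$h, net$J, beta = b), mode = "exact")
  }, numeric(1))
  # compare where Glauber dynamics still equilibrate: deep in the ordered
  # regime (large beta) the chain freezes and both estimators break down
  interior <- which(betas >= 0.12 & betas <= 2.1)
  expect_lt(max(abs(C_spline[interior] - C_exact[interior])) /
              max(C_exact), 0.05)
  # direct energy-variance estimate agrees too
  expect_lt(max(abs(sw$table$heat_capacity[interior] - C_exact[interior])) /
              max(C_exact), 0.05)
})

test_that("zipf curve ranks states and fits the top-mass slope", {
  z <- zipf_curve(fixture_generator("synthetic-zipf-counts", 100))
  expect_equal(z$slope, -1, tolerance = 1e-10)
  zu <- zipf_curve(rep(20, 32))
  expect_equal(zu$slope, 0, tolerance = 1e-10)
  expect_error(zipf_curve(c(0, 5, 0)), "at least 2")
  # fitted ranks cover 90% of the probability mass
  counts <- c(500, 300, 100, 50, 30, 10, 5, 3, 1, 1)
  z3 <- zipf_curve(counts)
  expect_gte(sum(z3$prob[seq_len(z3$n_fit)]), 0.9)
})

test_that("peak location takes the first maximum", {
  expect_equal(peak_location(1:5, c(0, 3, 9, 3, 0)), 3)
  expect_equal(peak_location(1:5, rep(2, 5)), 1)
  x <- beta_grid(21)
  expect_equal(peak_location(x, -(log(x))^2), 1)
  expect_error(peak_location(1:3, c(1, NA, 2)), "finite")
})

test_that("embodied beta sweep produces ordered entropies and is seeded", {
  net <- embodied_network(2)
  set.seed(61)
  net$J[net$mask] <- runif(sum(net$mask), -1, 1)
  net$J <- (net$J + t(net$J)) / 2
  net$J[!net$mask] <- 0
  betas <- c(0.1, 1, 10)
  sw <- run_sweep(net, "mountain_car", betas = betas,
                  n_sweeps_per_beta = 3000, reset_every = 1500,
                  subset = "hidden", seed = 62)
  expect_equal(colSums(sw$counts), rep(3000, 3))
  # disordered limit: near-uniform hidden states; ordered limit: frozen
  expect_gt(sw$table$entropy[1], 0.95 * 2 * log(2))
  expect_lt(sw$table$entropy[3], sw$table$entropy[1])
  sw2 <- run_sweep(net, "mountain_car", betas = betas,
                   n_sweeps_per_beta = 3000, reset_every = 1500,
                   subset = "hidden", seed = 62)
  expect_identical(sw$counts, sw2$counts)
  # histogramming refusal for oversized subsets
  expect_error(run_sweep(embodied_network(25), "mountain_car",
                         betas = 1, n_sweeps_per_beta = 10,
                         subset = "hidden"), "24")
})

test_that("a trained agent's behavioural susceptibility peaks near beta = 1", {
  fit <- study_agent()
  sw <- run_sweep(fit$net, "mountain_car", betas = beta_grid(21),
                  n_sweeps_per_beta = 5e4, reset_every = 5e4,
                  subset = "hidden", seed = 63)
  sw <- sweep_diagnostics(sw)
  # heat capacity and susceptibility both peak close to the operating point
  expect_lt(abs(log(sw$peak_beta)), log(1.6))
  expect_lt(abs(log(sw$peak_beta_susceptibility)), log(1.6))
})
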