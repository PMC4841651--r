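test_that("single step matches the hand-evaluated update rule", {
  p <- builtin_ions("K+")$params
  # origin is a fixed point of the noise-free drift
  st <- cg_step(cg_state_zero(), p, 1e-3, numeric(3))
  expect_equal(unlist(st[c("X", "V", "U", "Z")]), rep(0, 12),
               ignore_attr = TRUE)
  # unit velocity pushes acceleration by -eta1 * dt
  st <- list(t = 0, X = numeric(3), V = c(1, 0, 0), U = numeric(3),
             Z = numeric(3))
  st <- cg_step(st, p, 1e-3, numeric(3))
  expect_equal(st$U[1], -0.7687)
  expect_equal(st$X[1], 1e-3)
  expect_error(cg_step(list(t = 0, X = c(Inf, 0, 0), V = numeric(3),
                            U = numeric(3), Z = numeric(3)),
                       p, 1e-3, numeric(3)), "blow-up")
})

test_that("compiled simulator is bit-identical to the R-level reference loop", {
  p <- builtin_ions("K+")$params
  tr <- simulate_cg(p, n_steps = 200, seed = 7)
  set.seed(7)
  st <- cg_state_zero()
  for (k in 1:200) st <- cg_step(st, p, 1e-3, rnorm(3))
  expect_identical(unname(tr$V[201, ]), unname(st$V))
  expect_identical(unname(tr$Z[201, ]), unname(st$Z))
  # determinism contract and the zero-step edge case
  tr2 <- simulate_cg(p, n_steps = 200, seed = 7)
  expect_identical(tr$X, tr2$X)
  tr0 <- simulate_cg(p, n_steps = 0, seed = 1)
  expect_equal(tr0$n_steps, 0L)
  expect_equal(unname(tr0$X[1, ]), c(0, 0, 0))
})

test_that("stationary sampler has the stated diagonal covariance", {
  p <- builtin_ions("K+")$params
  v2s <- p$eta4^2 / (2 * p$eta1 * p$eta2 * p$eta3)
  set.seed(1)
  draws <- replicate(2e4, unlist(sample_stationary(p)))
  expect_lt(rel_err(mean(draws[1:3, ]^2), v2s), 0.03)
  expect_lt(rel_err(mean(draws[4:6, ]^2), p$eta1 * v2s), 0.03)
  expect_lt(rel_err(mean(draws[7:9, ]^2), p$eta1 * p$eta3 * v2s), 0.03)
  # cross-moment <VU> vanishes
  vu <- mean(draws[1, ] * draws[4, ])
  expect_lt(abs(vu) / sqrt(v2s * p$eta1 * v2s), 0.03)
  # unit-parameter case
  set.seed(2)
  v <- replicate(2e4, sample_stationary(cg_params(1, 2, 1, 2))$V[1])
  expect_lt(abs(var(v) - 1), 0.05)
})

test_that("moment estimators behave on constructed trajectories", {
  ones <- matrix(1, 11, 3)
  tr <- cg_traj(0.1, X = ones * 0, V = ones, U = ones * 0, Z = NULL)
  expect_equal(unname(estimate_moments(tr)["v2"]), 1)
  tr2 <- cg_traj(0.1, X = ones * 0, V = 2 * ones, U = ones * 0)
  expect_equal(unname(estimate_moments(tr2)["v2"]), 4)
  expect_error(estimate_moments(cg_traj(0.1, ones[1, , drop = FALSE],
                                        ones[1, , drop = FALSE],
                                        ones[1, , drop = FALSE])),
               "at least 2")
})

test_that("auxiliary-moment estimator isolates the stochastic forcing", {
  # two-step toy: unit jump in U over dt = 1 with V = 0
  tr <- cg_traj(1, X = matrix(0, 2, 3), V = matrix(0, 2, 3),
                U = rbind(rep(0, 3), rep(1, 3)))
  expect_equal(estimate_z2(tr, eta1 = 123), 1)
  # deterministic (noise-free) dynamics: the estimator returns exactly zero
  p <- builtin_ions("K+")$params
  n <- 500; dt <- 1e-4
  V <- U <- matrix(0, n + 1, 3)
  V[1, ] <- 1
  for (k in 1:n) {
    V[k + 1, ] <- V[k, ] + U[k, ] * dt
    U[k + 1, ] <- U[k, ] - p$eta1 * V[k, ] * dt
  }
  tr <- cg_traj(dt, X = matrix(0, n + 1, 3), V = V, U = U)
  expect_equal(estimate_z2(tr, p$eta1, burn_in = 0), 0)
  expect_error(estimate_z2(cg_traj(1, matrix(0, 1, 3), matrix(0, 1, 3),
                                   matrix(0, 1, 3)), 1), "too short")
})

test_that("MSD slope estimator recovers a known diffusion constant", {
  # Brownian oracle: increments drawn from the exact law with D = 0.5
  set.seed(11)
  D <- 0.5; dt <- 0.01; n <- 2e5
  X <- apply(matrix(rnorm(3 * n, sd = sqrt(2 * D * dt)), n, 3), 2, cumsum)
  tr <- cg_traj(dt, X = rbind(0, X), V = matrix(0, n + 1, 3),
                U = matrix(0, n + 1, 3))
  est <- estimate_D_msd(tr, fit_window = c(1, 5))
  expect_lt(rel_err(est$D, D), 0.05)
  expect_error(estimate_D_msd(tr, fit_window = c(1, 1e4)), "outside")
})

test_that("jerk map reproduces a constructed linear jerk field exactly", {
  p <- builtin_ions("K+")$params
  ve <- seq(-4, 4, by = 0.5)
  vmid <- (ve[-1] + ve[-length(ve)]) / 2
  # velocities sitting exactly at bin centres, jerk = -eta1 * v, u constant
  v <- rep(vmid, each = 30)
  n <- length(v)
  dt <- 1e-3
  vv <- rep(v, length.out = n + 1)
  V <- cbind(vv, vv, vv)
  U <- matrix(0, n + 1, 3)
  for (k in 1:n) U[k + 1, ] <- U[k, ] + (-p$eta1 * V[k, ]) * dt
  tr <- cg_traj(dt, X = matrix(0, n + 1, 3), V = V, U = U)
  jm <- jerk_map(tr, v_bins = ve, u_bins = 10)
  occ <- which(!is.na(jm$J2))
  expect_equal(jm$J2[occ], -p$eta1 * jm$v_mid[occ], tolerance = 1e-9)
  fit <- jerk_fit(jm)
  expect_equal(fit$slope, -p$eta1, tolerance = 1e-9)
  expect_lt(abs(fit$intercept), 1e-6)
  expect_error(jerk_map(tr, v_bins = c(0, 0, 0)), "degenerate")
})

test_that("simulated trajectories show the linear jerk law with slope -eta1", {
  p <- builtin_ions("K+")$params
  tr <- generate_surrogate(p, n_steps = 2e5, seed = 3)
  fit <- jerk_fit(jerk_map(tr))
  expect_lt(rel_err(fit$slope, -p$eta1), 0.05)
  expect_gt(fit$r_squared, 0.99)
})

test_that("Euler stepping carries a small O(dt) stationary bias, absent from the exact sampler", {
  p <- builtin_ions("K+")$params
  imp <- implied_stats(p)
  tre <- simulate_cg(p, init = "stationary", n_steps = 2e5, seed = 5,
                     method = "euler")
  me <- estimate_moments(tre)
  expect_lt(rel_err(me["u2"], imp$u2), 0.12)
  trx <- simulate_cg(p, init = "stationary", n_steps = 2e5, seed = 5,
                     method = "exact")
  mx <- estimate_moments(trx)
  expect_lt(rel_err(mx["v2"], imp$v2), 0.05)
  expect_lt(rel_err(mx["u2"], imp$u2), 0.05)
  expect_lt(rel_err(estimate_z2(trx, p$eta1), imp$z2), 0.10)
  # halving dt shrinks the Euler bias on the fast variable
  tre2 <- simulate_cg(p, init = "stationary", n_steps = 4e5, dt = 5e-4,
                      seed = 5, method = "euler")
  expect_lt(rel_err(estimate_moments(tre2)["u2"], imp$u2),
            rel_err(me["u2"], imp$u2))
})

test_that("noise-free relaxation decays to the origin", {
  # eta4 plays no role without noise: all components contract to zero
  p <- builtin_ions("K+")$params
  st <- list(t = 0, X = numeric(3), V = c(2, -1, 0.5), U = c(10, 0, 0),
             Z = c(0, 1e3, 0))
  for (k in 1:4000) st <- cg_step(st, p, 1e-3, numeric(3))
  expect_lt(max(abs(c(st$V, st$U, st$Z))), 1e-8)
})

test_that("Langevin one-step moment blow-up reproduces the printed comparison", {
  k <- builtin_ions("K+")$stats
  m <- langevin_moment_check(k, dt = 1e-3)
  expect_lt(rel_err(m, 4.44e5), 0.005)
  # the measured acceleration moment is two orders of magnitude smaller
  expect_gt(m / k$u2, 50)
  expect_lt(m / k$u2, 200)
  # large-dt limit drops the white-noise term
  expect_equal(langevin_moment_check(k, dt = 1e12), k$v2^3 / k$D^2,
               tolerance = 1e-6)
  expect_error(langevin_moment_check(k, dt = 0), "positive")
})

test_that("trajectory files round-trip exactly", {
  p <- builtin_ions("K+")$params
  tr <- simulate_cg(p, n_steps = 50, seed = 9)
  f <- withr::local_tempfile(fileext = ".txt")
  write_trajectory(tr, f)
  tr2 <- read_trajectory(f)
  expect_equal(tr2$X, tr$X, ignore_attr = TRUE)
  expect_equal(tr2$Z, tr$Z, ignore_attr = TRUE)
  expect_equal(tr2$dt, tr$dt)
  # byte-identical regeneration under the same seed
  f2 <- withr::local_tempfile(fileext = ".txt")
  write_trajectory(simulate_cg(p, n_steps = 50, seed = 9), f2)
  expect_identical(readLines(f), readLines(f2))
})
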