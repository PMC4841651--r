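test_that("drift eigenvalues match the published spectra for all ions", {
  for (ion in names(TAB_EIG)) {
    ds <- build_drift(builtin_ions(ion)$params)
    lam <- ds$eigenvalues
    ref <- TAB_EIG[[ion]]
    expect_lt(rel_err(Re(lam[1]), ref$real), 0.005)
    expect_lt(abs(Im(lam[1])), 1e-8)
    cp <- lam[Im(lam) > 0]
    expect_lt(rel_err(Re(cp), Re(ref$cplx)), 0.005)
    expect_lt(rel_err(Im(cp), Im(ref$cplx)), 0.005)
  }
})

test_that("spectrum satisfies the cubic's Vieta relations and the stability interval", {
  for (p in c(random_cg_params(20, seed = 3),
              lapply(builtin_ions(), `[[`, "params"))) {
    ds <- build_drift(p)
    lam <- ds$eigenvalues
    expect_equal(Re(sum(lam)), -p$eta2, tolerance = 1e-8)
    expect_equal(Re(prod(lam)), -p$eta1 * p$eta2,
                 tolerance = 1e-8)
    expect_true(all(Re(lam) > -p$eta2 & Re(lam) < 0))
  }
  # spectral gap: the real eigenvalue is the fastest for every built-in ion
  for (ion in names(TAB_EIG)) {
    lam <- build_drift(builtin_ions(ion)$params)$eigenvalues
    expect_lt(Re(lam[1]), Re(lam[2]))
    expect_equal(Re(lam[2]), Re(lam[3]))
  }
})

test_that("near-repeated spectra are rejected as degenerate", {
  # eta3 -> 0+ pushes two roots together only in contrived settings; instead
  # force degeneracy through the tolerance argument
  p <- builtin_ions("K+")$params
  expect_error(build_drift(p, tol = 1), "degenerate")
})

test_that("ten-moment system reaches the analytic steady state", {
  p <- builtin_ions("K+")$params
  imp <- implied_stats(p)
  out <- integrate_moments10(p, c(0.5, 2))
  fin <- out[2, ]
  expect_lt(rel_err(fin["XV"], imp$D), 1e-6)
  expect_lt(rel_err(fin["XU"], -imp$v2), 1e-6)
  expect_lt(rel_err(fin["XZ"], p$eta1 * imp$D), 1e-6)
  expect_lt(rel_err(fin["V2"], imp$v2), 2e-3)   # within rounding of Table 2
  expect_lt(rel_err(fin["V2"], 6.32), 2e-3)
  expect_lt(rel_err(fin["XZ"] / fin["XV"], p$eta1), 1e-5)
  expect_true(all(abs(fin[c("UV", "VZ", "UZ")]) <
                    1e-8 * max(abs(fin))))
  # short-time: only <Z2> moves at first (rate eta4^2)
  early <- integrate_moments10(p, 1e-6)
  expect_lt(rel_err(early[1, "Z2"], p$eta4^2 * 1e-6), 1e-3)
  expect_lt(max(abs(early[1, c("X2", "XV", "V2", "U2")])),
            1e-6 * early[1, "Z2"])
  expect_error(integrate_moments10(p, c(1, 0.5)), "increasing")
})

test_that("reduced four-moment system has the stationary-velocity structure", {
  p <- builtin_ions("K+")$params
  imp <- implied_stats(p)
  # initial growth rate of <XV> is the frozen stationary velocity variance
  tiny <- integrate_moments4_reduced(p, 1e-7)
  expect_lt(rel_err(tiny[1, "XV"] / 1e-7, imp$v2), 1e-4)
  # long-time slope of <X2> equals 2D
  out <- integrate_moments4_reduced(p, c(1, 1.1))
  slope <- (out[2, "X2"] - out[1, "X2"]) / 0.1
  expect_lt(rel_err(slope, 2 * imp$D), 1e-6)
})

test_that("MSD time shifts match the published table for all ions", {
  for (ion in names(TAB_SHIFT)) {
    p <- builtin_ions(ion)$params
    expect_lt(rel_err(msd_time_shift(p, "full10"), TAB_SHIFT[[ion]]["t1"]),
              0.02, label = paste("t1* for", ion))
    expect_lt(rel_err(msd_time_shift(p, "reduced4"), TAB_SHIFT[[ion]]["t2"]),
              0.02, label = paste("t2* for", ion))
  }
  # sign structure: zero start lags pure diffusion, stationary start leads it
  p <- builtin_ions("K+")$params
  expect_gt(msd_time_shift(p, "full10"), 0)
  expect_lt(msd_time_shift(p, "reduced4"), 0)
})

test_that("analytic VACF has the stationary value, Green-Kubo integral and decay", {
  for (ion in names(TAB_STATS)) {
    p <- builtin_ions(ion)$params
    imp <- implied_stats(p)
    tg <- seq(0, 2, by = 1e-3)
    C <- vacf_cg(p, tg)$C
    expect_equal(C[1], imp$v2, tolerance = 1e-12)
    integral <- sum(diff(tg) * (C[-1] + C[-length(C)]) / 2)
    expect_lt(rel_err(integral, imp$D), 1e-3)
    expect_lt(abs(C[length(C)]), 1e-6 * C[1])
  }
})

test_that("moment ODEs agree with the stochastic layer", {
  p <- builtin_ions("K+")$params
  n_steps <- 100; dt <- 1e-3
  ds <- build_drift(p)
  A <- rbind(c(0, 1, 0, 0), cbind(0, ds$B))
  Q <- matrix(0, 4, 4); Q[4, 4] <- p$eta4^2
  pr <- cgion:::exact_propagator(A, Q, dt)
  # the simulator's one-step recursion, applied to covariances, must solve
  # the moment ODEs (deterministic equivalence of the two layers)
  S <- matrix(0, 4, 4)
  for (k in seq_len(n_steps)) S <- pr$P %*% S %*% t(pr$P) + pr$L %*% t(pr$L)
  ode <- integrate_moments10(p, n_steps * dt)[1, ]
  expect_lt(rel_err(S[1, 1], ode["X2"]), 1e-6)
  expect_lt(rel_err(S[2, 2], ode["V2"]), 1e-6)
  expect_lt(rel_err(S[3, 3], ode["U2"]), 1e-6)
  expect_lt(rel_err(S[4, 4], ode["Z2"]), 1e-6)
  expect_lt(rel_err(S[1, 2], ode["XV"]), 1e-5)
  # and the simulator path is exactly that recursion (shared seed)
  tr <- simulate_cg(p, n_steps = 5, seed = 21, method = "exact")
  set.seed(21)
  y <- matrix(0, 4, 3)
  for (k in 1:5) for (i in 1:3)
    y[, i] <- pr$P %*% y[, i] + pr$L %*% rnorm(4)
  expect_equal(unname(tr$Z[6, ]), y[4, ], tolerance = 1e-12)
  # Monte-Carlo ensemble sits inside a 3-sigma band around the ODE solution
  n_rep <- 1e4
  set.seed(22)
  Y <- matrix(0, 4, 3 * n_rep)
  for (k in seq_len(n_steps))
    Y <- pr$P %*% Y + pr$L %*% matrix(rnorm(4 * 3 * n_rep), 4)
  per_rep <- function(row)
    colMeans(matrix(Y[row, ]^2, 3, n_rep))
  for (m in list(c(1, "X2"), c(2, "V2"), c(3, "U2"), c(4, "Z2"))) {
    vals <- per_rep(as.integer(m[1]))
    expect_lt(abs(mean(vals) - ode[m[2]]), 3 * sd(vals) / sqrt(n_rep),
              label = paste("ensemble vs ODE for", m[2]))
  }
})

test_that("analytic VACF matches the empirical VACF of a stationary run", {
  p <- builtin_ions("K+")$params
  tr <- simulate_cg(p, init = "stationary", n_steps = 2e5, seed = 13,
                    method = "exact")
  emp <- vacf_empirical(tr, max_lag = 200, origin_stride = 7)
  ana <- vacf_cg(p, emp$t)
  expect_lt(max(abs(emp$C - ana$C)), 0.08 * ana$C[1])
})
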