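test_that("BD step has the exact Brownian increment law", {
  bd <- bd_params(D = 0.183, dT = 0.5)
  expect_equal(bd_step(c(1, 2, 3), bd, numeric(3)), c(1, 2, 3))
  set.seed(1)
  inc <- replicate(2e4, bd_step(0, bd, rnorm(1)))
  expect_lt(rel_err(var(inc), 2 * 0.183 * 0.5), 0.05)
  expect_warning(bd_params(1, dT = 0.01), "dT")
  expect_error(bd_params(-1), "positive")
})

test_that("pure BD paths reproduce the free-diffusion MSD", {
  set.seed(2)
  D <- 0.183; dT <- 0.5; n_steps <- 2000; n_part <- 300
  X <- matrix(0, n_part, 3)
  for (k in seq_len(n_steps))
    X <- X + sqrt(2 * D * dT) * matrix(rnorm(3 * n_part), n_part, 3)
  msd <- mean(X^2)   # per-component
  expect_lt(rel_err(msd, 2 * D * n_steps * dT), 0.1)
})

test_that("half-space density is symmetric, mass-normalized and bin-integrable", {
  D <- 0.183; t <- 1e3; h <- 1
  x <- seq(-10, 10, by = 0.5)
  rho <- analytic_halfspace_density(x, t, D, h, n_total = 1e6)
  expect_equal(rho, rev(rho))
  total <- stats::integrate(analytic_halfspace_density, -Inf, Inf,
                            t = t, D = D, h = h, n_total = 1e6)$value
  expect_lt(rel_err(total, 1e6), 1e-6)
  # expected count in the central 2-A bin for the published configuration
  bin <- stats::integrate(analytic_halfspace_density, 0, 2,
                          t = t, D = D, h = h, n_total = 1e6)$value
  expect_lt(rel_err(bin, 4.16e4), 0.005)
  expect_error(analytic_halfspace_density(0, t = 0, D = D, h = h), "positive")
})

test_that("region classification uses closed nested boxes", {
  dec <- region_decomposition(24.83)
  L <- dec$L
  expect_equal(classify_region(c(0, 0, 0), dec), 1L)
  expect_equal(classify_region(c(L / 2, 0, 0), dec), 1L)  # boundary closure
  expect_equal(classify_region(c(L / 2 + 1e-9, 0, 0), dec), 2L)
  expect_equal(classify_region(c(0.65 * L, 0, 0), dec), 4L)
  expect_equal(classify_region(c(0, 0, 100), dec), 5L)
  expect_equal(classify_region(rbind(c(0, 0, 0), c(0, 0, 100)), dec),
               c(1L, 5L))
  expect_error(region_decomposition(-1), "positive")
})

test_that("region decomposition partitions space with the right shell volumes", {
  dec <- region_decomposition(24.83)
  set.seed(4)
  lim <- dec$r4 * 1.2
  X <- matrix(runif(3 * 4e4, -lim, lim), ncol = 3)
  reg <- classify_region(X, dec)
  expect_true(all(reg %in% 1:5))
  vol_box <- (2 * c(dec$r1, dec$r2, dec$r3, dec$r4))^3
  vol_shell <- c(vol_box[1], diff(vol_box))
  frac_ref <- vol_shell / (2 * lim)^3
  frac_obs <- tabulate(reg, 5)[1:4] / nrow(X)
  for (j in 1:4)
    expect_lt(abs(frac_obs[j] - frac_ref[j]),
              3 * sqrt(frac_ref[j] / nrow(X)) + 0.003)
})

test_that("distance attenuation follows the box geometry", {
  dec <- region_decomposition(24.83, omega = 10)
  inside <- attenuated_distance_args(c(2, 5), c(0, 0, 0), dec)
  expect_equal(inside$r_attenuated, c(2, 5))
  expect_false(inside$beyond_cutoff)
  expect_equal(inside$dist, 0)
  out <- attenuated_distance_args(2, c(dec$L / 2 + 3, 0, 0), dec)
  expect_equal(out$dist, 3)
  expect_equal(out$r_attenuated, 2 + 10 * 3)
  expect_true(out$beyond_cutoff)   # 30 >= L/2
  at_cut <- attenuated_distance_args(0, c(dec$r1 + dec$L / 20, 0, 0), dec)
  expect_true(at_cut$beyond_cutoff)    # omega * dist == L/2 exactly
})

test_that("hybrid stepping switches models by region with the stated re-entry policy", {
  dec <- region_decomposition(24.83)
  cg <- builtin_ions("K+")$params
  bd <- bd_params(implied_stats(cg)$D)
  # CG particle deep inside the CG region: one ordinary step, tag unchanged
  set.seed(5)
  p <- hybrid_particle(c(0.62 * dec$L, 0, 0), tag = "cg")
  p2 <- hybrid_step_cg_bd(p, cg, bd, 1e-3, dec)
  expect_equal(p2$tag, "cg")
  expect_equal(p2$t, 1e-3)
  # BD particle already inside region 3 switches to CG with zero auxiliaries
  bd_tiny <- suppressWarnings(bd_params(1e-20, dT = 0.5))
  p <- hybrid_particle(c(0, 0, 0), tag = "bd")
  p2 <- hybrid_step_cg_bd(p, cg, bd_tiny, 1e-3, dec, init_policy = "zero")
  expect_equal(p2$tag, "cg")
  expect_equal(p2$V, numeric(3))
  expect_equal(p2$Z, numeric(3))
  # overlap region keeps the current tag for both models
  x4 <- c((dec$r3 + dec$r4) / 2, 0, 0)
  pbd <- hybrid_step_cg_bd(hybrid_particle(x4, "bd"), cg, bd_tiny, 1e-3, dec)
  expect_equal(pbd$tag, "bd")
  pcg <- hybrid_step_cg_bd(hybrid_particle(x4, "cg"), cg, bd, 1e-3, dec)
  expect_equal(pcg$tag, "cg")
  expect_error(hybrid_step_cg_bd(hybrid_particle(c(0, 0, 0), "fine"),
                                 cg, bd, 1e-3, dec), "fine-model")
})

test_that("with switching disabled the hybrid stepper is the pure integrator", {
  dec <- region_decomposition(24.83)
  cg <- builtin_ions("K+")$params
  bd <- bd_params(implied_stats(cg)$D)
  set.seed(6)
  p <- hybrid_particle(c(0, 0, 0), tag = "cg")
  for (k in 1:50) p <- hybrid_step_cg_bd(p, cg, bd, 1e-3, dec,
                                         switching = FALSE)
  ref <- simulate_cg(cg, n_steps = 50, seed = 6)
  expect_identical(p$X, unname(ref$X[51, ]))
  expect_identical(p$Z, unname(ref$Z[51, ]))
  set.seed(6)
  q <- hybrid_particle(c(0, 0, 0), tag = "bd")
  for (k in 1:10) q <- hybrid_step_cg_bd(q, cg, bd, 1e-3, dec,
                                         switching = FALSE)
  set.seed(6)
  Xref <- c(0, 0, 0)
  for (k in 1:10) Xref <- Xref + sqrt(2 * bd$D * bd$dT) * rnorm(3)
  expect_identical(q$X, Xref)
})

test_that("half-space experiment conserves particles and nails degenerate cases", {
  cg <- builtin_ions("K+")$params
  res <- run_halfspace_experiment(cg, n_particles = 400, t_end = 20, seed = 8)
  expect_equal(sum(res$bins$count), 400)
  expect_lt(rel_err(sum(res$bins$analytic), 400), 1e-3)
  # zero-duration run: two delta bins at +/- h
  res0 <- run_halfspace_experiment(cg, n_particles = 100, t_end = 0, seed = 1)
  expect_equal(sum(res0$bins$count > 0), 2L)
  expect_equal(sort(res0$bins$count[res0$bins$count > 0]), c(50, 50))
  expect_error(run_halfspace_experiment(cg, n_particles = 3, t_end = 1),
               "even")
})

test_that("escape-time theory matches its closed form and scaling", {
  th0 <- escape_theory(0.183, 0)
  expect_equal(th0$mean, 0)
  r <- 4 * 24.83
  th <- escape_theory(0.183, r)
  expect_equal(th$mean, r^2 / (6 * 0.183), tolerance = 1e-12)
  expect_equal(th$sd, r^2 / (3 * sqrt(10) * 0.183), tolerance = 1e-12)
  expect_lt(rel_err(th$mean, 8.98e3), 0.005)
  expect_equal(th$ci95_hi - th$ci95_lo,
               2 * 1.96 * th$sd / 10, tolerance = 1e-12)
  # CI width scales as r^2
  th2 <- escape_theory(0.183, 2 * r)
  expect_equal((th2$ci95_hi - th2$ci95_lo) / (th$ci95_hi - th$ci95_lo), 4,
               tolerance = 1e-12)
  expect_error(escape_theory(-1, 1), "positive")
})

test_that("pure BD escape means fall inside the theoretical interval for all ions", {
  r_target <- 25
  for (ion in names(TAB_STATS)) {
    D <- builtin_ions(ion)$stats$D
    set.seed(17)
    n <- 100; dT <- 0.5
    times <- vapply(seq_len(n), function(i) {
      X <- c(0, 0, 0); t <- 0
      repeat {
        X <- X + sqrt(2 * D * dT) * rnorm(3)
        t <- t + dT
        if (sum(X^2) >= r_target^2) return(t)
      }
    }, numeric(1))
    th <- escape_theory(D, r_target, n)
    expect_gt(mean(times), th$ci95_lo)
    expect_lt(mean(times), th$ci95_hi)
  }
})

test_that("escape experiment records monotone, reproducible first-passage times", {
  dec <- region_decomposition(24.83)
  cg <- builtin_ions("K+")$params
  es <- escape_time_experiment(dec, cg, r_max = 25, n_realizations = 3,
                               seed = 19)
  es2 <- escape_time_experiment(dec, cg, r_max = 25, n_realizations = 3,
                                seed = 19)
  expect_identical(es$T, es2$T)
  for (i in seq_len(nrow(es$T))) {
    tt <- es$T[i, !is.na(es$T[i, ])]
    expect_true(all(diff(tt) >= 0))
  }
  expect_false(any(es$truncated))
  # a tiny time budget flags truncation
  est <- escape_time_experiment(dec, cg, r_max = 80, n_realizations = 1,
                                t_max = 1, seed = 20)
  expect_true(any(est$truncated))
})

test_that("R-level pluggable fine model reproduces the compiled protocol statistically", {
  # degenerate check: fine model = CG step; tiny geometry so the run is short
  dec <- region_decomposition(5)
  cg <- builtin_ions("K+")$params
  fine <- function(st, dt) cg_step(st, cg, dt, stats::rnorm(3))
  es <- escape_time_experiment(dec, cg, r_max = 8, n_realizations = 4,
                               fine_model = fine, seed = 23)
  expect_true(all(is.finite(es$T[, ncol(es$T)])))
  th <- escape_theory(implied_stats(cg)$D, 8, 4)
  expect_lt(mean(es$T[, ncol(es$T)]), th$mean * 5)
  expect_gt(mean(es$T[, ncol(es$T)]), th$mean / 5)
})
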