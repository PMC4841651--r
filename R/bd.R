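#' Brownian dynamics parameters
#'
#' @param D diffusion constant, A^2 ps^-1.
#' @param dT BD timestep, ps (default 0.5 ps; any larger timestep works as
#'   well). Warns when smaller than 0.1 ps, since the point of the BD layer
#'   is a timestep much larger than the fine-scale 1e-3 ps.
#' @return Object of class `"bd_params"`.
#' @export
bd_params <- function(D, dT = 0.5) {
  if (!is.finite(D) || D <= 0) stop("D must be positive")
  if (!is.finite(dT) || dT <= 0) stop("dT must be positive")
  if (dT < 0.1) warning("BD timestep dT < 0.1 ps: expected dT >> CG dt")
  structure(list(D = D, dT = dT), class = "bd_params")
}

#' One Brownian dynamics step
#'
#' \eqn{X(t+\Delta T) = X(t) + \sqrt{2D\Delta T}\,\xi} per component; exact
#' for Brownian motion at any timestep.
#'
#' @param X numeric position vector (any length).
#' @param bd a [bd_params()].
#' @param noise N(0,1) draws, same length as `X`.
#' @param dT optional override of the timestep (used for clock-aligned
#'   partial steps).
#' @return Updated position vector.
#' @export
bd_step <- function(X, bd, noise, dT = bd$dT) {
  stopifnot(inherits(bd, "bd_params"), length(noise) == length(X))
  X + sqrt(2 * bd$D * dT) * noise
}

#' Analytic half-space density
#'
#' Marginal density along x1 at time t of `n_total` Brownian particles, half
#' started at \eqn{(+h,0,0)} and half at \eqn{(-h,0,0)}:
#' \deqn{\varrho(x_1) = \frac{n_{\rm total}}{2\sqrt{4\pi D t}}\left[
#'   e^{-(x_1-h)^2/4Dt} + e^{-(x_1+h)^2/4Dt}\right],}
#' which integrates to `n_total` and is symmetric in x1. This is the
#' reference curve the hybrid CG/BD half-space experiment is compared with.
#'
#' @param x1 positions at which to evaluate, A.
#' @param t time, ps (> 0).
#' @param D diffusion constant, A^2 ps^-1.
#' @param h start offset, A.
#' @param n_total total particle count (mass of the density).
#' @return Density values, particles per A.
#' @export
analytic_halfspace_density <- function(x1, t, D, h, n_total = 1e6) {
  if (t <= 0) stop("t must be positive")
  n_total / (2 * sqrt(4 * pi * D * t)) *
    (exp(-(x1 - h)^2 / (4 * D * t)) + exp(-(x1 + h)^2 / (4 * D * t)))
}

#' Nested-box domain decomposition
#'
#' The computational domain is split into five pairwise-disjoint, exhaustive
#' regions built from nested, closed, origin-centred cubes: the fine-scale
#' (MD) core \eqn{\Omega_1 = [-L/2, L/2]^3}, the fine/CG hand-shaking shell
#' \eqn{\Omega_2} (outer half-width \eqn{L/2 + L/(2\omega)}), the CG shell
#' \eqn{\Omega_3} (adds \eqn{h_1}), the CG/BD hand-shaking shell
#' \eqn{\Omega_4} (adds \eqn{h_2}) and the unbounded BD region
#' \eqn{\Omega_5}. Defaults \eqn{\omega = 10}, \eqn{h_1 = L/20},
#' \eqn{h_2 = L/10} put the CG/BD switching boundaries at 0.6 L and 0.7 L
#' from the origin.
#'
#' @param L side of the inner box, A.
#' @param omega dimensionless attenuation parameter (also sets the
#'   \eqn{\Omega_2} width \eqn{L/(2\omega)}).
#' @param h1,h2 shell widths, A.
#' @return Object of class `"region_decomposition"` with the four outer
#'   half-widths `r1 < r2 < r3 < r4` of regions 1..4.
#' @export
#' @examples
#' region_decomposition(24.83)
region_decomposition <- function(L, omega = 10, h1 = L / 20, h2 = L / 10) {
  vals <- c(L = L, omega = omega, h1 = h1, h2 = h2)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all decomposition parameters must be positive")
  r <- cumsum(c(L / 2, L / (2 * omega), h1, h2))
  structure(list(L = L, omega = omega, h1 = h1, h2 = h2,
                 r1 = r[1], r2 = r[2], r3 = r[3], r4 = r[4]),
            class = "region_decomposition")
}

#' @export
print.region_decomposition <- function(x, ...) {
  cat(sprintf("Region decomposition: L = %g A, omega = %g, h1 = %g, h2 = %g\n",
              x$L, x$omega, x$h1, x$h2))
  cat(sprintf("  box half-widths: %.4g | %.4g | %.4g | %.4g A (region 5 outside)\n",
              x$r1, x$r2, x$r3, x$r4))
  invisible(x)
}

#' Classify a point into a region
#'
#' Regions are defined from closed nested boxes, so boundary points belong to
#' the inner region (a point at max-norm exactly L/2 is in region 1).
#'
#' @param X numeric 3-vector (or n x 3 matrix) of positions, A.
#' @param dec a [region_decomposition()].
#' @return Integer region id(s) in 1..5.
#' @export
classify_region <- function(X, dec) {
  stopifnot(inherits(dec, "region_decomposition"))
  X <- if (is.matrix(X)) X else matrix(X, ncol = 3)
  a <- apply(abs(X), 1L, max)
  unname(1L + (a > dec$r1) + (a > dec$r2) + (a > dec$r3) + (a > dec$r4))
}

#' Attenuated ion--water distance arguments
#'
#' When the ion sits outside the fine-scale core \eqn{\Omega_1}, the forces
#' it exerts on the explicit solvent are evaluated at distances inflated by
#' \eqn{\omega\,\mathrm{dist}(X, \Omega_1)} (the Euclidean distance from the
#' ion to the closed inner box; zero inside it). This continuously switches
#' the interaction off: once \eqn{\omega\,\mathrm{dist}(X,\Omega_1)} reaches
#' the force cutoff the interaction vanishes identically. Only this geometric
#' rule is implemented here; no solvent forces are evaluated.
#'
#' @param r raw ion--site distance(s), A (>= 0).
#' @param X ion position, 3-vector.
#' @param dec a [region_decomposition()].
#' @param cutoff force cutoff distance, A (default L/2).
#' @return List with `r_attenuated` (same shape as `r`), `dist` (distance
#'   from X to the inner box) and `beyond_cutoff`
#'   (`TRUE` when `omega * dist >= cutoff`).
#' @export
attenuated_distance_args <- function(r, X, dec, cutoff = dec$L / 2) {
  stopifnot(inherits(dec, "region_decomposition"), all(r >= 0))
  d <- sqrt(sum(pmax(abs(X) - dec$r1, 0)^2))
  list(r_attenuated = r + dec$omega * d, dist = d,
       beyond_cutoff = dec$omega * d >= cutoff)
}

#' Hybrid particle state
#'
#' Per-particle bookkeeping for the multiscale stepper: position, active
#' model tag and (when the tag is not `"bd"`) the CG auxiliary state.
#'
#' @param X position 3-vector, A.
#' @param tag one of `"fine"`, `"cg"`, `"bd"`.
#' @param V,U,Z auxiliary state 3-vectors (required unless `tag = "bd"`).
#' @param t particle clock, ps.
#' @return Object of class `"hybrid_particle"`.
#' @export
hybrid_particle <- function(X, tag = c("cg", "bd", "fine"),
                            V = numeric(3), U = numeric(3), Z = numeric(3),
                            t = 0) {
  tag <- match.arg(tag)
  p <- list(X = X, tag = tag, t = t)
  if (tag != "bd") { p$V <- V; p$U <- U; p$Z <- Z }
  structure(p, class = "hybrid_particle")
}

# region ids active per model in the CG/BD coupling: CG runs in 1..4 (enters
# BD only in region 5), BD runs in 4..5 (reverts to CG upon entering 1..3).
# In the overlap region 4 a particle keeps its current tag.
.hybrid_regions <- function(X, geometry) {
  if (inherits(geometry, "region_decomposition")) {
    reg <- classify_region(X, geometry)
    c(to_bd = reg == 5L, to_cg = reg <= 3L)
  } else {
    # half-space geometry: list(h = ...); regions split along x1
    h <- geometry$h
    c(to_bd = X[1] <= -h, to_cg = X[1] >= h)
  }
}

#' One step of the hybrid CG/BD protocol
#'
#' Advances a [hybrid_particle()] by one step of its active model and applies
#' the post-step switching rule: a CG particle that enters the BD-only
#' region drops its auxiliary state and becomes a BD particle; a BD particle
#' that enters the CG-only region becomes a CG particle with its auxiliary
#' state re-initialized either deterministically to zero (`init_policy =
#' "zero"`, the default protocol) or drawn from the stationary law
#' (`"stationary"`). Inside the hand-shaking overlap the particle keeps its
#' current tag. Switch detection is post-step (no interpolation to the
#' crossing time); the clock advances by `dt` for CG steps and `bd$dT` for
#' BD steps.
#'
#' @param p a [hybrid_particle()] with tag `"cg"` or `"bd"`.
#' @param cg a [cg_params()].
#' @param bd a [bd_params()].
#' @param dt CG timestep, ps.
#' @param geometry a [region_decomposition()], or `list(h = ...)` for the
#'   half-space geometry (CG-only at `x1 >= h`, BD-only at `x1 <= -h`).
#' @param init_policy `"zero"` or `"stationary"`.
#' @param switching set `FALSE` to disable all tag changes (the stepper then
#'   reduces exactly to the pure CG or pure BD integrator).
#' @return The advanced particle.
#' @export
hybrid_step_cg_bd <- function(p, cg, bd, dt, geometry,
                              init_policy = c("zero", "stationary"),
                              switching = TRUE) {
  stopifnot(inherits(p, "hybrid_particle"))
  init_policy <- match.arg(init_policy)
  if (p$tag == "fine")
    stop("fine-model particle reached the CG/BD stepper without a fine-model plug-in")
  if (p$tag == "cg") {
    st <- cg_step(list(t = p$t, X = p$X, V = p$V, U = p$U, Z = p$Z),
                  cg, dt, stats::rnorm(3))
    p$X <- st$X; p$V <- st$V; p$U <- st$U; p$Z <- st$Z; p$t <- st$t
    if (switching && .hybrid_regions(p$X, geometry)["to_bd"]) {
      p$tag <- "bd"; p$V <- p$U <- p$Z <- NULL
    }
  } else {
    p$X <- bd_step(p$X, bd, stats::rnorm(3))
    p$t <- p$t + bd$dT
    if (switching && .hybrid_regions(p$X, geometry)["to_cg"]) {
      p$tag <- "cg"
      if (init_policy == "stationary") {
        s <- sample_stationary(cg)
        p$V <- s$V; p$U <- s$U; p$Z <- s$Z
      } else {
        p$V <- p$U <- p$Z <- numeric(3)
      }
    }
  }
  p
}

#' Half-space hybrid CG/BD experiment
#'
#' The validation experiment for the CG-to-BD coupling: `n_particles`
#' particles, half started at \eqn{(+h,0,0)} under the CG model (zero
#' auxiliary state) and half at \eqn{(-h,0,0)} under BD, evolve to `t_end`
#' under the switching protocol of [hybrid_step_cg_bd()] in the half-space
#' geometry. The final x1 marginal histogram is returned together with the
#' analytic Brownian reference ([analytic_halfspace_density()]) integrated
#' over the same bins. Because the dynamics and the switching rule are
#' componentwise independent and only component 1 is observed, the
#' experiment is simulated along component 1 (distributionally exact).
#'
#' @param cg a [cg_params()].
#' @param bd a [bd_params()] (defaults to the CG model's implied D, dT 0.5).
#' @param h half-width of the overlap slab, A.
#' @param n_particles even particle count.
#' @param t_end final time, ps.
#' @param bin_width histogram bin width, A (default 2).
#' @param dt CG timestep, ps.
#' @param init_policy re-entry initialization, `"zero"` or `"stationary"`.
#' @param seed integer seed.
#' @return Object of class `"halfspace_result"`: data frame `bins`
#'   (`bin_lo`, `bin_hi`, `count`, `analytic`) plus fields `x1`, `t_end`,
#'   `n_particles`.
#' @export
run_halfspace_experiment <- function(cg, bd = NULL, h = 1, n_particles,
                                     t_end, bin_width = 2, dt = 1e-3,
                                     init_policy = c("zero", "stationary"),
                                     seed = NULL) {
  stopifnot(inherits(cg, "cg_params"))
  init_policy <- match.arg(init_policy)
  if (n_particles %% 2L != 0L) stop("n_particles must be even")
  D <- implied_stats(cg)$D
  if (is.null(bd)) bd <- bd_params(D)
  if (!is.null(seed)) set.seed(seed)
  n2 <- n_particles / 2L
  x0 <- c(rep(h, n2), rep(-h, n2))
  tag0 <- c(rep(0L, n2), rep(1L, n2))
  x1 <- if (t_end > 0) {
    cpp_halfspace(unlist(coef(cg)), bd$D, h, dt, bd$dT, t_end, x0, tag0,
                  match(init_policy, c("zero", "stationary")) - 1L,
                  stationary_sd(cg))
  } else x0
  lim <- max(abs(x1)) + bin_width
  breaks <- seq(-ceiling(lim / bin_width) * bin_width,
                ceiling(lim / bin_width) * bin_width, by = bin_width)
  counts <- graphics::hist(x1, breaks = breaks, plot = FALSE)$counts
  ana <- if (t_end > 0) {
    vapply(seq_len(length(breaks) - 1L), function(i)
      stats::integrate(analytic_halfspace_density, breaks[i], breaks[i + 1L],
                       t = t_end, D = bd$D, h = h,
                       n_total = n_particles)$value, numeric(1))
  } else rep(NA_real_, length(breaks) - 1L)
  structure(list(bins = data.frame(bin_lo = breaks[-length(breaks)],
                                   bin_hi = breaks[-1L],
                                   count = counts, analytic = ana),
                 x1 = x1, t_end = t_end, n_particles = n_particles,
                 D = bd$D, h = h),
            class = "halfspace_result")
}

#' @export
print.halfspace_result <- function(x, ...) {
  occ <- x$bins[x$bins$analytic >= 1 | x$bins$count > 0, ]
  dev <- abs(occ$count - occ$analytic) / sqrt(pmax(occ$analytic, 1))
  cat(sprintf("Half-space hybrid experiment: %d particles, t = %g ps\n",
              x$n_particles, x$t_end))
  cat(sprintf("  %d occupied bins, max |count - analytic|/sqrt(analytic) = %.2f\n",
              nrow(occ), max(dev)))
  invisible(x)
}

#' @export
plot.halfspace_result <- function(x, ...) {
  b <- x$bins
  mids <- (b$bin_lo + b$bin_hi) / 2
  plot(mids, b$count, type = "h", lwd = 3, col = "grey",
       xlab = "x1 [A]", ylab = "ions per bin", ...)
  graphics::lines(mids, b$analytic, col = "red")
  invisible(x)
}

#' Theoretical escape-time statistics for Brownian motion
#'
#' First-passage time T(r) of a Brownian particle from the centre of a ball
#' of radius r: mean \eqn{r^2/(6D)}, standard deviation
#' \eqn{r^2/(3\sqrt{10}\,D)}, and the normal 95% confidence interval for the
#' mean of `n` independent realizations,
#' \eqn{r^2/(6D) \pm 1.96\, r^2/(3\sqrt{10}\,D\,\sqrt{n})}.
#'
#' @param D diffusion constant, A^2 ps^-1.
#' @param r escape radius (may be a vector), A.
#' @param n number of realizations entering the sample mean (default 100).
#' @return Data frame with columns `r`, `mean`, `sd`, `ci95_lo`, `ci95_hi`
#'   (all times in ps).
#' @export
#' @examples
#' escape_theory(0.183, 4 * 24.83)   # K+ to 4L: mean ~ 8.98e3 ps
escape_theory <- function(D, r, n = 100) {
  if (D <= 0) stop("D must be positive")
  if (any(r < 0)) stop("r must be non-negative")
  m <- r^2 / (6 * D)
  s <- r^2 / (3 * sqrt(10) * D)
  half <- 1.96 * s / sqrt(n)
  data.frame(r = r, mean = m, sd = s, ci95_lo = m - half, ci95_hi = m + half)
}

#' Multiscale escape-time experiment
#'
#' Simulates trajectories started at the origin with the full region
#' decomposition until they first reach distance `r_max` from the origin,
#' recording for every realization the first-passage times T(r) on a grid of
#' radii. The fine-scale model plugged into regions 1--2 defaults to the CG
#' model itself (`fine_model = "cg"`, the bundled surrogate; the dynamics are
#' then CG everywhere inside the region-4 outer box and BD outside, which is
#' the configuration whose mean escape time is compared with
#' [escape_theory()]). A custom fine model can be supplied as a function
#' `function(state, dt)` advancing a CG-like state one step; it is applied
#' in regions 1--2 through a (slow) R-level loop intended for small tests.
#'
#' @param dec a [region_decomposition()].
#' @param cg a [cg_params()].
#' @param bd a [bd_params()]; default from the CG model's implied D.
#' @param r_max maximum escape radius, A (default `4 * dec$L`).
#' @param r_grid radii at which to record T(r); default 40 uniform radii
#'   from `dec$L / 10` to `r_max`.
#' @param n_realizations number of independent trajectories.
#' @param dt CG (and fine) timestep, ps.
#' @param t_max per-realization time budget, ps; realizations exceeding it
#'   are flagged `truncated`.
#' @param init_policy auxiliary-state re-entry policy, `"zero"` or
#'   `"stationary"`.
#' @param fine_model `"cg"` or a step function (see Details).
#' @param seed integer seed.
#' @return Object of class `"escape_result"`: list with `r_grid`, matrix `T`
#'   (realization x radius, ps), logical `truncated`, and `theory` (the
#'   [escape_theory()] table for `n_realizations`).
#' @export
escape_time_experiment <- function(dec, cg, bd = NULL, r_max = 4 * dec$L,
                                   r_grid = NULL, n_realizations = 100,
                                   dt = 1e-3, t_max = 1e6,
                                   init_policy = c("zero", "stationary"),
                                   fine_model = "cg", seed = NULL) {
  stopifnot(inherits(dec, "region_decomposition"), inherits(cg, "cg_params"))
  init_policy <- match.arg(init_policy)
  D <- implied_stats(cg)$D
  if (is.null(bd)) bd <- bd_params(D)
  if (is.null(r_grid)) r_grid <- seq(dec$L / 10, r_max, length.out = 40)
  r_grid <- sort(r_grid)
  if (!is.null(seed)) set.seed(seed)
  pol <- match(init_policy, c("zero", "stationary")) - 1L
  if (identical(fine_model, "cg")) {
    res <- cpp_escape(unlist(coef(cg)), bd$D, dt, bd$dT, dec$r4, dec$r3,
                      r_grid, as.integer(n_realizations), t_max, pol,
                      stationary_sd(cg))
    Tmat <- res$T; trunc <- as.logical(res$truncated)
  } else {
    if (!is.function(fine_model)) stop("fine_model must be \"cg\" or a function")
    Tmat <- matrix(NA_real_, n_realizations, length(r_grid))
    trunc <- logical(n_realizations)
    for (p in seq_len(n_realizations)) {
      st <- list(t = 0, X = numeric(3), V = numeric(3), U = numeric(3),
                 Z = numeric(3))
      tag <- "fine"; k <- 1L
      while (k <= length(r_grid)) {
        if (st$t > t_max) { trunc[p] <- TRUE; break }
        reg <- classify_region(st$X, dec)
        if (tag == "fine" && reg >= 3L) tag <- "cg"
        if (tag == "cg" && reg <= 2L) tag <- "fine"
        if (tag == "cg" && reg == 5L) tag <- "bd"
        if (tag == "bd" && reg <= 3L) {
          tag <- "cg"
          if (init_policy == "stationary") {
            s <- sample_stationary(cg)
            st$V <- s$V; st$U <- s$U; st$Z <- s$Z
          } else st$V <- st$U <- st$Z <- numeric(3)
        }
        st <- switch(tag,
          fine = fine_model(st, dt),
          cg = cg_step(st, cg, dt, stats::rnorm(3)),
          bd = { st$X <- bd_step(st$X, bd, stats::rnorm(3))
                 st$t <- st$t + bd$dT; st })
        r <- sqrt(sum(st$X^2))
        while (k <= length(r_grid) && r >= r_grid[k]) {
          Tmat[p, k] <- st$t; k <- k + 1L
        }
      }
    }
  }
  structure(list(r_grid = r_grid, T = Tmat, truncated = trunc,
                 theory = escape_theory(bd$D, r_grid, n_realizations),
                 n_realizations = n_realizations, D = bd$D),
            class = "escape_result")
}

#' @export
print.escape_result <- function(x, ...) {
  rmax <- x$r_grid[length(x$r_grid)]
  m <- mean(x$T[, ncol(x$T)], na.rm = TRUE)
  th <- x$theory[nrow(x$theory), ]
  cat(sprintf("Escape experiment: %d realizations to r = %.4g A\n",
              x$n_realizations, rmax))
  cat(sprintf("  mean T(r_max) = %.4g ps; theory %.4g ps, 95%% CI [%.4g, %.4g]\n",
              m, th$mean, th$ci95_lo, th$ci95_hi))
  if (any(x$truncated)) cat("  ", sum(x$truncated), "realizations truncated\n")
  invisible(x)
}
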