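#' Trajectory container
#'
#' A uniform-timestep time series of ion state vectors: position `X`,
#' velocity `V`, acceleration `U` and (optionally) the auxiliary variable `Z`,
#' each an (n_steps+1) x 3 matrix in A / ps units. Produced by
#' [simulate_cg()], [simulate_fp()] and [generate_surrogate()], and consumed
#' by the moment estimators ([estimate_moments()], [estimate_z2()],
#' [estimate_D_msd()], [jerk_map()]).
#'
#' @param dt timestep, ps (> 0).
#' @param X,V,U matrices with one row per stored step and 3 columns.
#' @param Z optional auxiliary-variable matrix (may be `NULL`).
#' @param seed RNG seed used to generate the trajectory, or `NA`.
#' @param aux optional list of extra per-step arrays (e.g. fictitious-particle
#'   internals), carried along untouched.
#' @return An object of class `"cg_traj"`.
#' @export
cg_traj <- function(dt, X, V, U, Z = NULL, seed = NA_integer_, aux = NULL) {
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) stop("dt must be positive")
  X <- as.matrix(X); V <- as.matrix(V); U <- as.matrix(U)
  n <- nrow(X)
  if (nrow(V) != n || nrow(U) != n || (!is.null(Z) && nrow(as.matrix(Z)) != n))
    stop("all state columns must have equal length")
  structure(list(dt = dt, n_steps = n - 1L, t = (seq_len(n) - 1) * dt,
                 X = X, V = V, U = U,
                 Z = if (is.null(Z)) NULL else as.matrix(Z),
                 seed = seed, aux = aux),
            class = "cg_traj")
}

#' @export
print.cg_traj <- function(x, ...) {
  cat(sprintf("Trajectory: %d steps, dt = %g ps (span %.4g ps)\n",
              x$n_steps, x$dt, x$n_steps * x$dt))
  cat("  columns: X, V, U", if (!is.null(x$Z)) ", Z", "\n", sep = "")
  if (!is.na(x$seed)) cat("  seed:", x$seed, "\n")
  invisible(x)
}

#' @export
as.data.frame.cg_traj <- function(x, ...) {
  d <- data.frame(t = x$t,
                  x1 = x$X[, 1], x2 = x$X[, 2], x3 = x$X[, 3],
                  v1 = x$V[, 1], v2 = x$V[, 2], v3 = x$V[, 3],
                  u1 = x$U[, 1], u2 = x$U[, 2], u3 = x$U[, 3])
  if (!is.null(x$Z)) {
    d$z1 <- x$Z[, 1]; d$z2 <- x$Z[, 2]; d$z3 <- x$Z[, 3]
  }
  d
}

#' Write / read a trajectory as delimited text
#'
#' One row per stored step, space-delimited, header line naming the columns
#' `t x1..x3 v1..v3 u1..u3 [z1..z3]`; units A and ps throughout. Values are
#' written with full (17 significant digit) precision so write-then-read
#' round-trips exactly.
#'
#' @param traj a [cg_traj()] object.
#' @param file output path.
#' @return `read_trajectory()` returns a [cg_traj()]; `write_trajectory()`
#'   returns `file`, invisibly.
#' @export
write_trajectory <- function(traj, file) {
  stopifnot(inherits(traj, "cg_traj"))
  d <- as.data.frame(traj)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste(names(d), collapse = " "), con)
  m <- as.matrix(d)
  txt <- apply(format(m, digits = 17, scientific = TRUE, trim = TRUE), 1L,
               paste, collapse = " ")
  writeLines(txt, con)
  invisible(file)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(file) {
  d <- utils::read.table(file, header = TRUE)
  need <- c("t", paste0("x", 1:3), paste0("v", 1:3), paste0("u", 1:3))
  if (!all(need %in% names(d))) stop("malformed trajectory file: missing columns")
  if (nrow(d) < 2L) stop("trajectory too short: need at least 2 rows")
  dts <- diff(d$t)
  dt <- stats::median(dts)
  if (any(abs(dts - dt) > 1e-8 * max(dt, 1))) stop("non-uniform timestep")
  Z <- if (all(paste0("z", 1:3) %in% names(d)))
    as.matrix(d[paste0("z", 1:3)]) else NULL
  cg_traj(dt, as.matrix(d[paste0("x", 1:3)]), as.matrix(d[paste0("v", 1:3)]),
          as.matrix(d[paste0("u", 1:3)]), Z)
}

.burn_rows <- function(traj, burn_in) {
  n <- nrow(traj$V)
  from <- min(n - 1L, floor(burn_in * n)) + 1L
  seq.int(from, n)
}

#' Estimate stationary second moments from a trajectory
#'
#' Time-and-component averages of the squared velocity and acceleration,
#' the empirical counterparts of the stationary moments used by
#' [fit_cg_params()]. An initial fraction of the series can be discarded as
#' equilibration burn-in.
#'
#' @param traj a [cg_traj()].
#' @param burn_in fraction of initial rows to discard (default 0.1).
#' @return Named vector `c(v2 = ..., u2 = ...)` in A^2 ps^-2 / A^2 ps^-4.
#' @export
estimate_moments <- function(traj, burn_in = 0.1) {
  stopifnot(inherits(traj, "cg_traj"))
  if (nrow(traj$V) < 2L) stop("empty trajectory: need at least 2 steps")
  idx <- .burn_rows(traj, burn_in)
  c(v2 = mean(traj$V[idx, ]^2), u2 = mean(traj$U[idx, ]^2))
}

#' Estimate the auxiliary-variable second moment from a trajectory
#'
#' Finite-difference estimator
#' \deqn{\langle Z^2\rangle \approx \left\langle\left(
#'   \frac{U(t+\Delta t) - U(t)}{\Delta t} + \eta_1 V(t)\right)^2\right\rangle,}
#' averaged over steps and components: the one-step rate of change of
#' acceleration with its deterministic part removed.
#'
#' @param traj a [cg_traj()] with `V` and `U` columns.
#' @param eta1 velocity relaxation coefficient, ps^-2 (typically from
#'   `u2/v2` of [estimate_moments()]).
#' @param burn_in fraction of initial rows to discard.
#' @return Scalar estimate of \eqn{\langle Z^2\rangle}, A^2 ps^-6.
#' @export
estimate_z2 <- function(traj, eta1, burn_in = 0.1) {
  stopifnot(inherits(traj, "cg_traj"))
  n <- nrow(traj$U)
  if (n < 2L) stop("trajectory too short: need at least 2 steps")
  idx <- .burn_rows(traj, burn_in)
  idx <- idx[idx < n]
  du <- (traj$U[idx + 1L, , drop = FALSE] - traj$U[idx, , drop = FALSE]) / traj$dt
  mean((du + eta1 * traj$V[idx, , drop = FALSE])^2)
}

#' Estimate the diffusion constant from mean square displacement
#'
#' Computes the time-averaged, component-averaged mean square displacement
#' \eqn{\langle X^2\rangle(t)} (averaging over sliding time origins) and fits
#' a least-squares line over a time window chosen past the ballistic/
#' oscillatory transient; D is half the slope. The window default `[1, 5]` ps
#' is far beyond the model's slowest relaxation times (|Re lambda| >= ~12/ps
#' for the built-in ions).
#'
#' @param traj a [cg_traj()].
#' @param fit_window numeric length-2, lag window (ps) for the linear fit.
#' @param n_lags number of lag points in the window.
#' @param origin_stride use every k-th row as a time origin (controls cost).
#' @return List with `D` (A^2 ps^-1), `lags`, `msd`, `fit_window`.
#' @export
estimate_D_msd <- function(traj, fit_window = c(1, 5), n_lags = 40,
                           origin_stride = NULL) {
  stopifnot(inherits(traj, "cg_traj"))
  span <- traj$n_steps * traj$dt
  if (fit_window[2] > span + 1e-12) stop("fit window outside trajectory span")
  lag_steps <- unique(round(seq(fit_window[1], fit_window[2],
                                length.out = n_lags) / traj$dt))
  lag_steps <- lag_steps[lag_steps >= 1 & lag_steps <= traj$n_steps]
  if (length(lag_steps) < 2L) stop("fewer than 2 lag points in window")
  n <- nrow(traj$X)
  if (is.null(origin_stride))
    origin_stride <- max(1L, floor(n / 2000))
  msd <- vapply(lag_steps, function(k) {
    org <- seq.int(1L, n - k, by = origin_stride)
    mean((traj$X[org + k, , drop = FALSE] - traj$X[org, , drop = FALSE])^2)
  }, numeric(1))
  lags <- lag_steps * traj$dt
  fit <- stats::lm.fit(cbind(1, lags), msd)
  list(D = unname(fit$coefficients[2]) / 2, lags = lags, msd = msd,
       fit_window = fit_window)
}

#' Conditional mean jerk map of a trajectory
#'
#' Bins the one-step rate of change of acceleration ("jerk"),
#' \eqn{(U(t+\Delta t)-U(t))/\Delta t}, by the current velocity and
#' acceleration \eqn{(V(t), U(t))}, pooling all three components. For the CG
#' model the conditional mean jerk is exactly \eqn{J(v,u) = -\eta_1 v},
#' independent of u, so the profiles returned here should be linear in v.
#'
#' @param traj a [cg_traj()].
#' @param v_bins,u_bins either bin counts (scalar) or explicit edge vectors.
#'   Default: 40 uniform bins spanning +/- 4 standard deviations.
#' @return An object of class `"jerk_map"`: list with `v_edges`, `u_edges`,
#'   `mean_jerk` (v x u matrix, `NA` where unoccupied), `counts`,
#'   `v_mid`, `J1` (slice at the u-bin containing 0) and `J2`
#'   (occupancy-weighted average over u).
#' @export
jerk_map <- function(traj, v_bins = 40, u_bins = 40) {
  stopifnot(inherits(traj, "cg_traj"))
  n <- nrow(traj$U)
  if (n < 2L) stop("trajectory too short for jerk estimation")
  v <- as.vector(traj$V[-n, ])
  u <- as.vector(traj$U[-n, ])
  jerk <- as.vector(traj$U[-1L, ] - traj$U[-n, ]) / traj$dt
  edges <- function(x, b) {
    if (length(b) > 1L) return(sort(b))
    s <- sqrt(mean(x^2))
    seq(-4 * s, 4 * s, length.out = b + 1L)
  }
  ve <- edges(v, v_bins); ue <- edges(u, u_bins)
  if (length(ve) < 3L || length(ue) < 3L || any(diff(ve) <= 0) || any(diff(ue) <= 0))
    stop("degenerate bin grid")
  iv <- findInterval(v, ve, rightmost.closed = TRUE)
  iu <- findInterval(u, ue, rightmost.closed = TRUE)
  keep <- iv >= 1L & iv <= length(ve) - 1L & iu >= 1L & iu <= length(ue) - 1L
  iv <- iv[keep]; iu <- iu[keep]; jerk <- jerk[keep]
  nv <- length(ve) - 1L; nu <- length(ue) - 1L
  cell <- (iu - 1L) * nv + iv
  sums <- rowsum(jerk, cell)
  cnts <- rowsum(rep(1, length(cell)), cell)
  counts <- matrix(0, nv, nu)
  counts[as.integer(rownames(cnts))] <- cnts
  mj <- matrix(NA_real_, nv, nu)
  mj[as.integer(rownames(sums))] <- sums / cnts
  u0 <- findInterval(0, ue, rightmost.closed = TRUE)
  J1 <- mj[, u0]
  wt <- counts
  J2 <- rowSums(ifelse(is.na(mj), 0, mj) * wt) / pmax(rowSums(wt), 1)
  J2[rowSums(wt) == 0] <- NA_real_
  structure(list(v_edges = ve, u_edges = ue, mean_jerk = mj, counts = counts,
                 v_mid = (ve[-1] + ve[-length(ve)]) / 2, J1 = J1, J2 = J2),
            class = "jerk_map")
}

#' @export
print.jerk_map <- function(x, ...) {
  cat(sprintf("Jerk map: %d v-bins x %d u-bins, %d occupied cells\n",
              length(x$v_mid), length(x$u_edges) - 1L, sum(x$counts > 0)))
  invisible(x)
}

#' Linear fit of the averaged jerk profile
#'
#' Occupancy-weighted least-squares regression of the u-averaged jerk profile
#' `J2(v)` on v. For a CG trajectory the slope estimates \eqn{-\eta_1} and the
#' intercept is zero.
#'
#' @param jm a [jerk_map()].
#' @return List with `slope`, `intercept`, `r_squared`.
#' @export
jerk_fit <- function(jm) {
  stopifnot(inherits(jm, "jerk_map"))
  ok <- !is.na(jm$J2)
  w <- rowSums(jm$counts)[ok]
  v <- jm$v_mid[ok]; y <- jm$J2[ok]
  fit <- stats::lm.wfit(cbind(1, v), y, w)
  yhat <- fit$fitted.values
  ybar <- sum(w * y) / sum(w)
  r2 <- 1 - sum(w * (y - yhat)^2) / sum(w * (y - ybar)^2)
  list(slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]), r_squared = r2)
}

#' Second moment of the one-step Langevin acceleration
#'
#' For Langevin dynamics \eqn{dV = -\gamma V dt + \gamma\sqrt{2D}\,dW}
#' parametrized to match a given diffusion constant and velocity variance
#' (\eqn{\gamma = \langle V^2\rangle / D}), the discretized one-step
#' acceleration \eqn{(V(t+\Delta t)-V(t))/\Delta t} has second moment
#' \deqn{\frac{\langle V^2\rangle^3}{D^2} +
#'       \frac{2\langle V^2\rangle^2}{D\,\Delta t}.}
#' For ions in water this exceeds the measured \eqn{\langle U^2\rangle} by
#' about two orders of magnitude (the random force decorrelates much more
#' slowly than one timestep), which is why Langevin dynamics is unsuitable as
#' the intermediate model and the four-parameter CG model is used instead.
#'
#' @param stats an [md_stats()] (only `D` and `v2` are used).
#' @param dt timestep, ps.
#' @return Scalar second moment, A^2 ps^-4.
#' @export
#' @examples
#' langevin_moment_check(builtin_ions("K+")$stats, dt = 1e-3)
langevin_moment_check <- function(stats, dt) {
  stopifnot(inherits(stats, "md_stats"))
  if (dt <= 0) stop("dt must be positive")
  stats$v2^3 / stats$D^2 + 2 * stats$v2^2 / (stats$D * dt)
}
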