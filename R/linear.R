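#' Drift system of the (V, U, Z) subsystem
#'
#' Assembles the 3x3 drift matrix and noise loading of the linear SDE
#' \eqn{dy = B y\,dt + b\,dW} with \eqn{y = (V, U, Z)^T},
#' \deqn{B = \begin{pmatrix} 0 & 1 & 0\\ -\eta_1 & 0 & 1\\
#'       0 & -\eta_3 & -\eta_2\end{pmatrix},\qquad b = (0, 0, \eta_4)^T,}
#' and computes its eigen-decomposition. The characteristic polynomial is
#' \eqn{\lambda^3 + \eta_2\lambda^2 + (\eta_1+\eta_3)\lambda + \eta_1\eta_2},
#' so for positive parameters all eigenvalue real parts are negative and lie
#' in \eqn{(-\eta_2, 0)}; the spectrum is one real root plus a complex
#' conjugate pair, and must be distinct.
#'
#' @param params a [cg_params()].
#' @param tol relative tolerance for the repeated-eigenvalue check.
#' @return An object of class `"drift_system"`: list with `B`, `b`,
#'   `eigenvalues` (complex, ordered by decreasing |Re|), `eigenvectors`,
#'   and `params`.
#' @export
#' @examples
#' build_drift(builtin_ions("K+")$params)$eigenvalues
build_drift <- function(params, tol = 1e-8) {
  stopifnot(inherits(params, "cg_params"))
  B <- matrix(c(0, 1, 0,
                -params$eta1, 0, 1,
                0, -params$eta3, -params$eta2), 3, 3, byrow = TRUE)
  b <- c(0, 0, params$eta4)
  es <- eigen(B)
  lam <- es$values
  if (any(Re(lam) >= 0))
    stop("unstable drift: eigenvalue with non-negative real part")
  dmin <- min(abs(c(lam[1] - lam[2], lam[1] - lam[3], lam[2] - lam[3])))
  if (dmin < tol * max(abs(lam))) stop("degenerate spectrum")
  ord <- order(abs(Re(lam)), decreasing = TRUE)
  structure(list(B = B, b = b, eigenvalues = lam[ord],
                 eigenvectors = es$vectors[, ord, drop = FALSE],
                 params = params),
            class = "drift_system")
}

#' @export
print.drift_system <- function(x, ...) {
  cat("CG drift system (V, U, Z)\n  eigenvalues [1/ps]: ")
  cat(format(x$eigenvalues, digits = 4), sep = "  ")
  cat("\n")
  invisible(x)
}

# 10x10 coefficient matrix + forcing of the closed second-moment ODE system,
# moment order: X2, XV, XU, XZ, V2, UV, VZ, U2, UZ, Z2.
moment10_system <- function(params) {
  e1 <- params$eta1; e2 <- params$eta2; e3 <- params$eta3; e4 <- params$eta4
  A <- matrix(0, 10, 10)
  A[1, 2] <- 2
  A[2, 5] <- 1; A[2, 3] <- 1
  A[3, 6] <- 1; A[3, 2] <- -e1; A[3, 4] <- 1
  A[4, 7] <- 1; A[4, 4] <- -e2; A[4, 3] <- -e3
  A[5, 6] <- 2
  A[6, 8] <- 1; A[6, 5] <- -e1; A[6, 7] <- 1
  A[7, 9] <- 1; A[7, 7] <- -e2; A[7, 6] <- -e3
  A[8, 6] <- -2 * e1; A[8, 9] <- 2
  A[9, 10] <- 1; A[9, 7] <- -e1; A[9, 9] <- -e2; A[9, 8] <- -e3
  A[10, 10] <- -2 * e2; A[10, 9] <- -2 * e3
  q <- numeric(10); q[10] <- e4^2
  list(A = A, q = q,
       names = c("X2", "XV", "XU", "XZ", "V2", "UV", "VZ", "U2", "UZ", "Z2"))
}

.integrate_linear <- function(A, q, y0, t_grid, rtol = 1e-10) {
  if (any(diff(t_grid) <= 0) || t_grid[1] < 0)
    stop("t_grid must be increasing and start at >= 0")
  grid <- if (t_grid[1] > 0) c(0, t_grid) else t_grid
  scale <- max(abs(y0), abs(q), 1)
  out <- deSolve::ode(y = y0, times = grid,
                      func = function(t, y, p) list(as.vector(A %*% y + q)),
                      parms = NULL, method = "lsoda",
                      rtol = rtol, atol = rtol * scale)
  out[match(t_grid, out[, 1]), -1, drop = FALSE]
}

#' Integrate the full ten-moment ODE system
#'
#' The CG model is linear, so its per-component second moments close into a
#' ten-dimensional linear ODE system (moments
#' \eqn{\langle X^2\rangle, \langle XV\rangle, \langle XU\rangle,
#' \langle XZ\rangle, \langle V^2\rangle, \langle UV\rangle,
#' \langle VZ\rangle, \langle U^2\rangle, \langle UZ\rangle,
#' \langle Z^2\rangle}). At steady state the cross moments
#' \eqn{\langle UV\rangle, \langle UZ\rangle, \langle VZ\rangle} vanish and
#' \eqn{\langle XV\rangle = D}, \eqn{\langle XU\rangle = -\langle V^2\rangle},
#' \eqn{\langle XZ\rangle = \eta_1 D}.
#'
#' @param params a [cg_params()].
#' @param t_grid increasing time grid (ps) starting at >= 0.
#' @param init numeric length-10 initial moments (default all zero,
#'   i.e. deterministic zero initial conditions).
#' @param rtol solver relative tolerance (stiff-capable lsoda).
#' @return Matrix, length(t_grid) x 10, with named columns.
#' @export
integrate_moments10 <- function(params, t_grid, init = numeric(10),
                                rtol = 1e-10) {
  stopifnot(inherits(params, "cg_params"), length(init) == 10L)
  sys <- moment10_system(params)
  out <- .integrate_linear(sys$A, sys$q, init, t_grid, rtol)
  colnames(out) <- sys$names
  out
}

#' Integrate the reduced four-moment ODE system
#'
#' When the (V, U, Z) subsystem is started from (and hence stays in) its
#' stationary law, \eqn{\langle V^2\rangle} is frozen at
#' \eqn{\eta_4^2/(2\eta_1\eta_2\eta_3)} and the position moments close into
#' four ODEs for \eqn{\langle X^2\rangle, \langle XV\rangle,
#' \langle XU\rangle, \langle XZ\rangle} (zero initial conditions).
#'
#' @inheritParams integrate_moments10
#' @return Matrix, length(t_grid) x 4, with named columns.
#' @export
integrate_moments4_reduced <- function(params, t_grid, rtol = 1e-10) {
  stopifnot(inherits(params, "cg_params"))
  e1 <- params$eta1; e2 <- params$eta2; e3 <- params$eta3
  v2s <- params$eta4^2 / (2 * e1 * e2 * e3)
  A <- matrix(0, 4, 4)
  A[1, 2] <- 2
  A[2, 3] <- 1
  A[3, 2] <- -e1; A[3, 4] <- 1
  A[4, 4] <- -e2; A[4, 3] <- -e3
  q <- c(0, v2s, 0, 0)
  out <- .integrate_linear(A, q, numeric(4), t_grid, rtol)
  colnames(out) <- c("X2", "XV", "XU", "XZ")
  out
}

#' Asymptotic MSD time shift relative to pure diffusion
#'
#' For large times the CG mean square displacement behaves as
#' \eqn{\langle X^2\rangle(t) \approx 2D\,(t - t^*)}: the model matches the
#' Brownian law up to a constant time shift. `variant = "full10"` integrates
#' the full ten-moment system from zero initial conditions (all state
#' variables deterministically zero; this shift is positive, the model first
#' has to build up velocity); `variant = "reduced4"` freezes the velocity
#' variance at its stationary value (stationary re-entry; this shift is
#' negative). The shift is evaluated as \eqn{t - \langle X^2\rangle(t)/(2D)}
#' at `t_eval`, with a convergence assertion against `t_eval/2` (transients
#' decay like exp(Re lambda t) with |Re lambda| >= ~12/ps, so 1 ps is far
#' into the asymptotic regime).
#'
#' @param params a [cg_params()].
#' @param variant `"full10"` or `"reduced4"`.
#' @param t_eval evaluation time, ps.
#' @param conv_tol maximum allowed |shift(t_eval) - shift(t_eval/2)|, ps.
#' @return Scalar time shift, ps.
#' @export
#' @examples
#' msd_time_shift(builtin_ions("K+")$params, "full10")    # ~ +3.1e-2 ps
#' msd_time_shift(builtin_ions("K+")$params, "reduced4")  # ~ -9.4e-3 ps
msd_time_shift <- function(params, variant = c("full10", "reduced4"),
                           t_eval = 1, conv_tol = 1e-4) {
  variant <- match.arg(variant)
  D <- implied_stats(params)$D
  tg <- c(t_eval / 2, t_eval)
  msd <- switch(variant,
    full10 = integrate_moments10(params, tg)[, "X2"],
    reduced4 = integrate_moments4_reduced(params, tg)[, "X2"])
  shift <- tg - msd / (2 * D)
  if (abs(shift[2] - shift[1]) > conv_tol)
    stop("MSD shift not converged at t_eval; increase t_eval")
  unname(shift[2])
}

# propagate v_{k+1} = expm(B*dt) v_k along a uniform grid; returns first row
# of each state.  Falls back to per-point expm for non-uniform grids.
.expm_profile <- function(B, v0, t_grid) {
  n <- length(t_grid)
  out <- numeric(n)
  dts <- diff(t_grid)
  uniform <- n >= 2L && all(abs(dts - dts[1]) < 1e-12 * max(dts[1], 1e-12))
  if (t_grid[1] == 0) {
    out[1] <- v0[1]
    start <- 2L
    v <- v0
  } else {
    v <- as.vector(.expm(B * t_grid[1]) %*% v0)
    out[1] <- v[1]
    start <- 2L
  }
  if (n == 1L) return(out)
  if (uniform) {
    P <- .expm(B * dts[1])
    for (k in start:n) {
      v <- as.vector(P %*% v)
      out[k] <- v[1]
    }
  } else {
    for (k in start:n)
      out[k] <- (.expm(B * t_grid[k]) %*% v0)[1]
  }
  out
}

#' Analytic velocity autocorrelation function of the CG model
#'
#' \deqn{C(t) = e_1^T e^{Bt} (\langle V^2\rangle, 0, 0)^T,}
#' computed by scaling-and-squaring matrix exponentials (numerically robust
#' even for nearly degenerate spectra; on a uniform grid a single propagator
#' is reused). \eqn{C(0) = \langle V^2\rangle} and by the Green--Kubo formula
#' \eqn{\int_0^\infty C(t)\,dt = D}.
#'
#' @param params a [cg_params()].
#' @param t_grid non-negative times, ps.
#' @return Data frame with columns `t` and `C` (A^2 ps^-2).
#' @export
vacf_cg <- function(params, t_grid) {
  stopifnot(inherits(params, "cg_params"), all(t_grid >= 0))
  ds <- build_drift(params)
  v2s <- implied_stats(params)$v2
  data.frame(t = t_grid, C = .expm_profile(ds$B, c(v2s, 0, 0), t_grid))
}

#' Empirical velocity autocorrelation function of a trajectory
#'
#' Time- and component-averaged estimator of \eqn{C(t) = \langle V(t)V(0)
#' \rangle} at lags `0..max_lag` steps, using sliding time origins.
#'
#' @param traj a [cg_traj()].
#' @param max_lag maximum lag in steps.
#' @param origin_stride time-origin subsampling stride.
#' @return Data frame with columns `t` and `C`.
#' @export
vacf_empirical <- function(traj, max_lag, origin_stride = 1L) {
  stopifnot(inherits(traj, "cg_traj"))
  n <- nrow(traj$V)
  if (max_lag >= n) stop("max_lag exceeds trajectory length")
  org <- seq.int(1L, n - max_lag, by = origin_stride)
  C <- vapply(0:max_lag, function(k)
    mean(traj$V[org, , drop = FALSE] * traj$V[org + k, , drop = FALSE]),
    numeric(1))
  data.frame(t = (0:max_lag) * traj$dt, C = C)
}

#' @export
plot.cg_params <- function(x, t_max = 1, n = 201, ...) {
  v <- vacf_cg(x, seq(0, t_max, length.out = n))
  plot(v$t, v$C, type = "l", xlab = "t [ps]",
       ylab = "C(t) [A^2/ps^2]",
       main = paste("CG velocity autocorrelation",
                    if (nzchar(x$ion)) paste0("(", x$ion, ")")), ...)
  graphics::abline(h = 0, lty = 3)
  invisible(v)
}

# scaling-and-squaring matrix exponential (dense, small systems)
.expm <- function(M) as.matrix(Matrix::expm(M))

.trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
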