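#' Fictitious-particle model parameters
#'
#' A hierarchy of heat-bath models generalizing the CG ion model: N
#' fictitious particles, each harmonically coupled to the ion, damped and
#' driven by independent noise. Particle j is characterized by four positive
#' constants \eqn{(\alpha_{j,1}, \alpha_{j,2}, \alpha_{j,3}, \alpha_{j,4})}
#' with units (ps^-2, ps^-1, ps^-2, A ps^-3/2). In the transformed
#' coordinates \eqn{\tilde U_j = \alpha_{j,1}(\tilde X_j - X)},
#' \eqn{\tilde Z_j = \alpha_{j,1}\tilde V_j} the model reads
#' \deqn{dV = \textstyle\sum_j \tilde U_j\,dt,\quad
#'   d\tilde U_j = (\tilde Z_j - \alpha_{j,1} V)\,dt,\quad
#'   d\tilde Z_j = -(\alpha_{j,2}\tilde Z_j + \alpha_{j,3}\tilde U_j)\,dt
#'   + \alpha_{j,1}\alpha_{j,4}\,dW_j,}
#' and for N = 1 coincides with the CG model under
#' \eqn{\eta_{1,2,3} = \alpha_{1,(1,2,3)}},
#' \eqn{\eta_4 = \alpha_{1,1}\alpha_{1,4}} (see [cg_to_fp()]).
#'
#' @param alpha numeric N x 4 matrix (or length-4 vector for N = 1) of
#'   positive coefficients, one row per fictitious particle.
#' @return Object of class `"fict_params"`.
#' @export
fict_params <- function(alpha) {
  if (is.null(dim(alpha))) alpha <- matrix(alpha, nrow = 1)
  alpha <- as.matrix(alpha)
  if (ncol(alpha) != 4L) stop("alpha must have four columns")
  if (any(!is.finite(alpha)) || any(alpha <= 0))
    stop("all alpha coefficients must be finite and positive")
  colnames(alpha) <- paste0("alpha", 1:4)
  structure(list(N = nrow(alpha), alpha = alpha), class = "fict_params")
}

#' @export
print.fict_params <- function(x, ...) {
  cat(sprintf("Fictitious-particle model, N = %d\n", x$N))
  print(signif(x$alpha, 4))
  invisible(x)
}

#' @export
coef.fict_params <- function(object, ...) object$alpha

#' Published N = 3 fictitious-particle parameter sets
#'
#' The N = 3 coefficient sets used to fit the fine-scale velocity
#' autocorrelation functions of K+ and Na+, transcribed from the published
#' figure captions.
#'
#' @param ion `"K+"` or `"Na+"`.
#' @return A [fict_params()] with N = 3.
#' @export
builtin_fp <- function(ion = c("K+", "Na+")) {
  ion <- match.arg(ion)
  a <- switch(ion,
    "K+" = rbind(c(5.64e2, 73.8,    3.42e3,  80.9),
                 c(1.26e2, 21.3,    7.27e2,  3.43e-1),
                 c(72.1,   2.02e2,  3.26e-1, 1.22e2)),
    "Na+" = rbind(c(3.05e3, 3.08e2, 8.99e3,  98.7),
                  c(96.5,   2.48e2, 4.62e2,  15.8),
                  c(23.5,   25.5,   3.82e2,  1.18e3)))
  fict_params(a)
}

#' Extended drift system of the fictitious-particle model
#'
#' Assembles the (2N+1)-dimensional drift matrix of the transformed state
#' \eqn{\tilde y = (V, \tilde U_1, \tilde Z_1, \ldots, \tilde U_N,
#' \tilde Z_N)^T}: the velocity row couples with coefficient 1 to every
#' \eqn{\tilde U_j}, and block j carries \eqn{-\alpha_{j,1}} (on V),
#' \eqn{-\alpha_{j,3}} and \eqn{-\alpha_{j,2}}. Noise enters row
#' \eqn{\tilde Z_j} with coefficient \eqn{\alpha_{j,1}\alpha_{j,4}} from N
#' independent channels. Stability (all eigenvalue real parts negative) and
#' spectrum distinctness are asserted.
#'
#' @param fp a [fict_params()].
#' @param tol relative tolerance for the degeneracy check.
#' @return Object of class `"ext_drift"`: list with `Btilde`, `btilde`
#'   (noise loading matrix, one column per channel), `Q`
#'   (= btilde btilde^T), `eigenvalues`, `N`.
#' @export
build_extended <- function(fp, tol = 1e-10) {
  stopifnot(inherits(fp, "fict_params"))
  N <- fp$N; m <- 2L * N + 1L
  B <- matrix(0, m, m)
  btilde <- matrix(0, m, N)
  for (j in seq_len(N)) {
    iu <- 2L * j; iz <- 2L * j + 1L
    B[1, iu] <- 1
    B[iu, 1] <- -fp$alpha[j, 1]
    B[iu, iz] <- 1
    B[iz, iu] <- -fp$alpha[j, 3]
    B[iz, iz] <- -fp$alpha[j, 2]
    btilde[iz, j] <- fp$alpha[j, 1] * fp$alpha[j, 4]
  }
  lam <- eigen(B, only.values = TRUE)$values
  if (any(Re(lam) >= 0)) stop("unstable extended drift")
  dmat <- abs(outer(lam, lam, "-"))
  if (min(dmat[upper.tri(dmat)]) < tol * max(abs(lam)))
    stop("degenerate spectrum")
  structure(list(Btilde = B, btilde = btilde, Q = btilde %*% t(btilde),
                 eigenvalues = lam[order(abs(Re(lam)), decreasing = TRUE)],
                 N = N),
            class = "ext_drift")
}

#' @export
print.ext_drift <- function(x, ...) {
  cat(sprintf("Extended drift, N = %d (%d x %d)\n  Re(eigenvalues) in [%.4g, %.4g] 1/ps\n",
              x$N, nrow(x$Btilde), ncol(x$Btilde),
              min(Re(x$eigenvalues)), max(Re(x$eigenvalues))))
  invisible(x)
}

# continuous Lyapunov equation B S + S B' = -Q via Kronecker vectorization
# (systems here are at most ~15-dimensional).
solve_lyapunov <- function(B, Q) {
  m <- nrow(B)
  S <- matrix(solve(diag(m) %x% B + B %x% diag(m), -as.vector(Q)), m, m)
  (S + t(S)) / 2
}

#' Stationary covariance of the fictitious-particle model
#'
#' Solves the continuous Lyapunov equation
#' \eqn{\tilde B S + S \tilde B^T = -\tilde b \tilde b^T} for the stationary
#' covariance of the extended state; the (1,1) entry is the model's
#' stationary \eqn{\langle V^2\rangle}.
#'
#' @param ed an [build_extended()] result (or a [fict_params()], which is promoted).
#' @return Symmetric (2N+1) x (2N+1) covariance matrix.
#' @export
stationary_covariance <- function(ed) {
  if (inherits(ed, "fict_params")) ed <- build_extended(ed)
  stopifnot(inherits(ed, "ext_drift"))
  solve_lyapunov(ed$Btilde, ed$Q)
}

#' Analytic velocity autocorrelation of the fictitious-particle model
#'
#' \deqn{C(t) = e_1^T e^{\tilde B t}\,S e_1,} where \eqn{S e_1} is the first
#' column of the stationary covariance (the equilibrium cross-covariances of
#' V with the full state). Computed with real matrix exponentials; on a
#' uniform grid a single propagator is reused.
#'
#' @param fp a [fict_params()].
#' @param t_grid non-negative times, ps.
#' @return Data frame with columns `t`, `C`.
#' @export
vacf_fp <- function(fp, t_grid) {
  stopifnot(inherits(fp, "fict_params"), all(t_grid >= 0))
  ed <- build_extended(fp)
  S <- stationary_covariance(ed)
  data.frame(t = t_grid, C = .expm_profile(ed$Btilde, S[, 1], t_grid))
}

#' Moments implied by a fictitious-particle model
#'
#' Stationary \eqn{\langle V^2\rangle} (the (1,1) covariance entry),
#' stationary \eqn{\langle U^2\rangle} of the physical acceleration
#' \eqn{dV/dt = \sum_j \tilde U_j} (the sum of the \eqn{\tilde U}-block of
#' the covariance), and the Green--Kubo diffusion constant
#' \eqn{D = \int_0^\infty C(t)\,dt = -e_1^T \tilde B^{-1} S e_1} in closed
#' form.
#'
#' @param fp a [fict_params()].
#' @return Named vector `c(D, v2, u2)`.
#' @export
fp_moments <- function(fp) {
  ed <- build_extended(fp)
  S <- stationary_covariance(ed)
  iu <- 2L * seq_len(ed$N)
  c(D = -drop(solve(ed$Btilde, S[, 1]))[1],
    v2 = S[1, 1],
    u2 = sum(S[iu, iu]))
}

#' Green--Kubo diffusion constant of the fictitious-particle model
#'
#' @param fp a [fict_params()].
#' @return Scalar D, A^2 ps^-1.
#' @export
diffusion_fp <- function(fp) unname(fp_moments(fp)["D"])

#' Map between the CG model and the N = 1 fictitious-particle model
#'
#' The CG model is the N = 1 member of the fictitious-particle hierarchy
#' under \eqn{\alpha_{1,1} = \eta_1}, \eqn{\alpha_{1,2} = \eta_2},
#' \eqn{\alpha_{1,3} = \eta_3}, \eqn{\alpha_{1,4} = \eta_4/\eta_1}; the
#' mapped models are pathwise identical under common random numbers.
#'
#' @param cg a [cg_params()].
#' @return `cg_to_fp()`: a [fict_params()] with N = 1;
#'   `fp_to_cg()`: a [cg_params()].
#' @export
cg_to_fp <- function(cg) {
  stopifnot(inherits(cg, "cg_params"))
  fict_params(c(cg$eta1, cg$eta2, cg$eta3, cg$eta4 / cg$eta1))
}

#' @rdname cg_to_fp
#' @param fp a [fict_params()] with N = 1.
#' @export
fp_to_cg <- function(fp) {
  stopifnot(inherits(fp, "fict_params"))
  if (fp$N != 1L) stop("fp_to_cg requires N = 1")
  a <- fp$alpha[1, ]
  cg_params(a[1], a[2], a[3], a[1] * a[4])
}

#' Simulate the fictitious-particle model
#'
#' Euler--Maruyama integration in the transformed coordinates
#' (V, \eqn{\tilde U_j}, \eqn{\tilde Z_j}), with N independent noise
#' channels per component drawn in a fixed (step, particle, component)
#' order. For N = 1 and a CG-mapped parameter set the velocity path is
#' bit-identical to [simulate_cg()] under the same seed.
#'
#' @param fp a [fict_params()].
#' @param init optional named list with `X`, `V` (3-vectors) and `Ut`, `Zt`
#'   (N x 3 matrices); default all zero. Use `"stationary"` to draw the
#'   extended state from its stationary law.
#' @param dt timestep, ps.
#' @param n_steps step count.
#' @param seed integer seed.
#' @param method `"euler"` (default) or `"exact"` (exact Gaussian one-step
#'   propagator, as in [simulate_cg()]; the exact path stores no
#'   per-particle internals beyond `Ut`).
#' @return A [cg_traj()] whose `U` column is the physical acceleration
#'   \eqn{\sum_j \tilde U_j}; the per-particle internals are in `$aux`.
#' @export
simulate_fp <- function(fp, init = NULL, dt = 1e-3, n_steps, seed = NULL,
                        method = c("euler", "exact")) {
  stopifnot(inherits(fp, "fict_params"), n_steps >= 0)
  method <- match.arg(method)
  N <- fp$N
  if (!is.null(seed)) set.seed(seed)
  if (identical(init, "stationary")) {
    S <- stationary_covariance(fp)
    R <- chol(S + diag(1e-12 * max(diag(S)), nrow(S)))
    y <- t(R) %*% matrix(stats::rnorm(3 * nrow(S)), nrow(S), 3)
    init <- list(X = numeric(3), V = y[1, ],
                 Ut = matrix(y[2L * seq_len(N), ], N, 3),
                 Zt = matrix(y[2L * seq_len(N) + 1L, ], N, 3))
  }
  if (is.null(init))
    init <- list(X = numeric(3), V = numeric(3),
                 Ut = matrix(0, N, 3), Zt = matrix(0, N, 3))
  sd_tag <- if (is.null(seed)) NA_integer_ else seed
  if (method == "euler") {
    ivec <- c(init$X, init$V, as.vector(t(init$Ut)), as.vector(t(init$Zt)))
    res <- cpp_simulate_fp(fp$alpha, ivec, dt, as.integer(n_steps))
    return(cg_traj(dt, res$X, res$V, res$U, Z = NULL, seed = sd_tag,
                   aux = list(Ut = res$Ut, Zt = res$Zt, N = N)))
  }
  ed <- build_extended(fp)
  m <- 2L * N + 2L
  A <- rbind(c(0, 1, rep(0, m - 2L)), cbind(0, ed$Btilde))
  Q <- rbind(0, cbind(0, ed$Q))
  pr <- exact_propagator(A, Q, dt)
  # per-component state order (X, V, Ut_1, Zt_1, ..., Ut_N, Zt_N)
  comp_state <- function(i) c(init$X[i], init$V[i],
                              as.vector(rbind(init$Ut[, i], init$Zt[, i])))
  y0 <- c(comp_state(1), comp_state(2), comp_state(3))
  out <- cpp_simulate_exact(pr$P, pr$L, y0, as.integer(n_steps))
  pick <- function(i) out[, c(i, i + m, i + 2L * m), drop = FALSE]
  iu <- 2L + 2L * seq_len(N) - 1L  # Ut rows within a component block
  U <- pick(iu[1])
  if (N > 1L) for (j in 2:N) U <- U + pick(iu[j])
  cg_traj(dt, pick(1L), pick(2L), U, Z = NULL, seed = sd_tag,
          aux = list(N = N))
}
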