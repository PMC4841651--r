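#' Generate a surrogate fine-scale trajectory
#'
#' Stands in for an all-atom simulation: generates a stationary-initialized
#' trajectory of a reference stochastic model (CG or fictitious-particle)
#' sampled at the fine-scale timestep (default 1e-3 ps), suitable for
#' exercising the estimation pipeline ([recover_params_pipeline()]) without
#' any external data. Reproducible by seed; optionally written to the
#' delimited trajectory format of [write_trajectory()].
#'
#' @param reference a [cg_params()] or [fict_params()] object.
#' @param n_steps step count; a warning is issued below 1e3 (too short for
#'   estimation use).
#' @param dt timestep, ps.
#' @param seed integer seed.
#' @param file optional output path; when given, the trajectory is written
#'   there and the path returned invisibly.
#' @param method simulation scheme, by default `"exact"` (the exact Gaussian
#'   propagator), so that the surrogate's stationary moments equal the
#'   reference model's prescription at any timestep; see [simulate_cg()].
#' @return A [cg_traj()] (invisibly the file path when `file` is given).
#' @export
generate_surrogate <- function(reference, n_steps, dt = 1e-3, seed = 1L,
                               file = NULL, method = c("exact", "euler")) {
  method <- match.arg(method)
  if (n_steps < 1e3) warning("n_steps < 1000: too short for estimation use")
  traj <- if (inherits(reference, "cg_params")) {
    simulate_cg(reference, init = "stationary", dt = dt, n_steps = n_steps,
                seed = seed, method = method)
  } else if (inherits(reference, "fict_params")) {
    simulate_fp(reference, init = "stationary", dt = dt, n_steps = n_steps,
                seed = seed, method = method)
  } else stop("reference must be cg_params or fict_params")
  if (!is.null(file)) {
    write_trajectory(traj, file)
    return(invisible(file))
  }
  traj
}

#' Recover statistics and CG parameters from a fine-scale trajectory
#'
#' The end-to-end estimation pipeline: stationary second moments of velocity
#' and acceleration by time-and-component averaging (after burn-in), the
#' auxiliary-variable moment by the one-step finite-difference estimator
#' ([estimate_z2()] with \eqn{\eta_1 = \hat u_2/\hat v_2}), the diffusion
#' constant from the mean square displacement slope over `fit_window`, and
#' finally the closed-form parameter map [fit_cg_params()]. Standard errors
#' of the moment estimates are obtained by block averaging (`n_blocks`
#' contiguous blocks).
#'
#' @param traj a [cg_traj()] or the path of a trajectory file.
#' @param burn_in fraction of initial rows discarded from moment averages.
#' @param fit_window MSD fit window, ps (default `c(1, 5)`).
#' @param n_blocks number of blocks for the standard errors.
#' @param min_steps minimum usable trajectory length.
#' @return Object of class `"cg_recovery"`: list with `stats`
#'   ([md_stats()]), `params` ([cg_params()]), `se` (block standard errors
#'   of v2, u2, z2) and `diagnostics`.
#' @export
recover_params_pipeline <- function(traj, burn_in = 0.1,
                                    fit_window = c(1, 5), n_blocks = 10,
                                    min_steps = 100) {
  if (is.character(traj)) traj <- read_trajectory(traj)
  stopifnot(inherits(traj, "cg_traj"))
  if (traj$n_steps < min_steps)
    stop("trajectory too short: ", traj$n_steps, " steps (need >= ", min_steps, ")")
  if (fit_window[2] > traj$n_steps * traj$dt)
    stop("trajectory too short for the MSD fit window [",
         fit_window[1], ", ", fit_window[2], "] ps")
  mom <- estimate_moments(traj, burn_in)
  eta1_hat <- unname(mom["u2"] / mom["v2"])
  z2_hat <- estimate_z2(traj, eta1_hat, burn_in)
  msd <- estimate_D_msd(traj, fit_window)
  stats <- md_stats(ion = "", D = msd$D, v2 = unname(mom["v2"]),
                    u2 = unname(mom["u2"]), z2 = z2_hat)
  params <- fit_cg_params(stats)
  # block-averaged standard errors of the stationary moment estimates
  idx <- .burn_rows(traj, burn_in)
  blocks <- split(idx, cut(seq_along(idx), n_blocks, labels = FALSE))
  bk <- vapply(blocks, function(ii) {
    ii2 <- ii[ii < nrow(traj$U)]
    du <- (traj$U[ii2 + 1L, , drop = FALSE] - traj$U[ii2, , drop = FALSE]) / traj$dt
    c(v2 = mean(traj$V[ii, ]^2), u2 = mean(traj$U[ii, ]^2),
      z2 = mean((du + eta1_hat * traj$V[ii2, , drop = FALSE])^2))
  }, numeric(3))
  se <- apply(bk, 1L, stats::sd) / sqrt(n_blocks)
  structure(list(stats = stats, params = params, se = se,
                 diagnostics = list(burn_in = burn_in,
                                    fit_window = fit_window,
                                    n_blocks = n_blocks,
                                    msd = msd[c("lags", "msd")],
                                    n_steps = traj$n_steps, dt = traj$dt)),
            class = "cg_recovery")
}

#' @export
print.cg_recovery <- function(x, ...) {
  cat("Parameter recovery from fine-scale trajectory\n")
  cat(sprintf("  %d steps at dt = %g ps; burn-in %g, MSD window [%g, %g] ps\n",
              x$diagnostics$n_steps, x$diagnostics$dt, x$diagnostics$burn_in,
              x$diagnostics$fit_window[1], x$diagnostics$fit_window[2]))
  cat(sprintf("  D = %#.4g   v2 = %#.4g (+/- %.2g)   u2 = %#.4g (+/- %.2g)   z2 = %#.4g (+/- %.2g)\n",
              x$stats$D, x$stats$v2, x$se["v2"], x$stats$u2, x$se["u2"],
              x$stats$z2, x$se["z2"]))
  cat(sprintf("  eta = (%#.4g, %#.4g, %#.4g, %#.4g)\n",
              x$params$eta1, x$params$eta2, x$params$eta3, x$params$eta4))
  invisible(x)
}
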