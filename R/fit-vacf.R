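# ---- constrained acceptance-rejection VACF fitting ------------------------
#
# The three moment constraints (D, <V2>, <U2>) are restored exactly after
# every random perturbation by three exact re-scalings of the coefficient
# matrix:
#   * noise scale  (all alpha_j4 * c):    (D, v2, u2) -> c^2 (D, v2, u2)
#   * time scale   (alpha_j1 * s^2, alpha_j2 * s, alpha_j3 * s^2,
#                   alpha_j4 * s^(3/2)): (D, v2, u2) -> (s D, s^2 v2, s^4 u2)
#   * coupling scale (all alpha_j1 * g), solved by 1-D root finding to match
#     the dimensionless invariant  delta = D^2 u2 / v2^3  (for N = 1 this
#     dial leaves D unchanged and scales v2, u2 by g, g^2).
# The two closed-form scalings then pin v2 and u2, and delta-matching makes
# D follow exactly.

fp_try_moments <- function(alpha) {
  tryCatch(fp_moments(fict_params(alpha)), error = function(e) NULL)
}

.fp_delta <- function(m) unname(m["D"]^2 * m["u2"] / m["v2"]^3)

project_fp_constraints <- function(alpha, target, tol = 1e-9) {
  delta_t <- unname(target["D"]^2 * target["u2"] / target["v2"]^3)
  f <- function(lg) {
    a <- alpha; a[, 1] <- a[, 1] * exp(lg)
    m <- fp_try_moments(a)
    if (is.null(m)) return(NA_real_)
    log(.fp_delta(m) / delta_t)
  }
  # bracket the root in log of the coupling scale
  lo <- 0; hi <- 0; flo <- f(0)
  if (is.na(flo)) return(NULL)
  if (abs(flo) > 0) {
    step <- if (flo > 0) 0.5 else -0.5   # delta decreases with the coupling
    hi <- step; fhi <- f(hi)
    k <- 0
    while (!is.na(fhi) && sign(fhi) == sign(flo) && k < 40) {
      lo <- hi; flo <- f(lo)
      hi <- hi + step; fhi <- f(hi)
      k <- k + 1
    }
    if (is.na(fhi) || sign(fhi) == sign(flo)) return(NULL)
    lg <- stats::uniroot(f, c(min(lo, hi), max(lo, hi)), tol = 1e-13)$root
    alpha[, 1] <- alpha[, 1] * exp(lg)
  }
  m <- fp_try_moments(alpha)
  if (is.null(m)) return(NULL)
  s <- sqrt((target["u2"] / target["v2"]) / (m["u2"] / m["v2"]))
  alpha[, 1] <- alpha[, 1] * s^2
  alpha[, 2] <- alpha[, 2] * s
  alpha[, 3] <- alpha[, 3] * s^2
  alpha[, 4] <- alpha[, 4] * s^1.5
  m <- fp_try_moments(alpha)
  if (is.null(m)) return(NULL)
  alpha[, 4] <- alpha[, 4] * sqrt(target["v2"] / m["v2"])
  m <- fp_try_moments(alpha)
  if (is.null(m)) return(NULL)
  if (max(abs(m[c("D", "v2", "u2")] / target[c("D", "v2", "u2")] - 1)) > tol)
    return(NULL)
  list(alpha = alpha, moments = m)
}

.l1_error <- function(t, c1, c2) .trapz(t, abs(c1 - c2))

#' Fit a fictitious-particle model to a velocity autocorrelation function
#'
#' Constrained acceptance--rejection search: starting from an initial
#' parameter set satisfying the three moment constraints (diffusion constant
#' D, \eqn{\langle V^2\rangle}, \eqn{\langle U^2\rangle}), the 4N
#' coefficients are perturbed log-normally, projected back onto the
#' constraint manifold exactly (see the file header: a coupling rescaling
#' solved by 1-D root finding plus closed-form time and noise rescalings),
#' and the proposal is accepted iff the L1 error between the model VACF and
#' the target decreases. The step size is annealed (halved after
#' `anneal_after` consecutive rejections). Every accepted iterate satisfies
#' the constraints to better than `constraint_tol` relative; the error trace
#' is non-increasing by construction.
#'
#' @param target data frame with columns `t` (uniform, ps) and `C`
#'   (A^2 ps^-2): the VACF to approximate. `C[1]` should equal the `v2`
#'   constraint if the target is itself a consistent stationary VACF.
#' @param constraints named vector `c(D = , v2 = , u2 = )`, all positive.
#' @param N number of fictitious particles.
#' @param seed integer seed.
#' @param max_iter proposal budget.
#' @param init_fp optional [fict_params()] starting point (projected onto
#'   the constraints before use); by default a jittered replication of the
#'   CG-mapped model implied by the constraints.
#' @param sigma initial log-normal perturbation scale.
#' @param anneal_after consecutive rejections before halving `sigma`.
#' @param constraint_tol maximum relative constraint violation accepted.
#' @param init_tries attempts at finding a stable constrained initializer.
#' @return Object of class `"vacf_fit"`: list with `params`
#'   ([fict_params()]), `trace` (accepted L1 errors, non-increasing),
#'   `l1` (final error), `moments`, `constraints`, `target`, `accepted`,
#'   `iterations`.
#' @export
fit_vacf <- function(target, constraints, N, seed = NULL, max_iter = 1000,
                     init_fp = NULL, sigma = 0.05, anneal_after = 50,
                     constraint_tol = 1e-6, init_tries = 200) {
  stopifnot(is.data.frame(target), all(c("t", "C") %in% names(target)),
            all(constraints[c("D", "v2", "u2")] > 0), N >= 1)
  if (!is.null(seed)) set.seed(seed)
  tgt <- constraints[c("D", "v2", "u2")]
  tt <- target$t; Ct <- target$C

  eval_prop <- function(alpha) {
    proj <- project_fp_constraints(alpha, tgt, tol = constraint_tol * 1e-3)
    if (is.null(proj)) return(NULL)
    C <- tryCatch(vacf_fp(fict_params(proj$alpha), tt)$C,
                  error = function(e) NULL)
    if (is.null(C)) return(NULL)
    proj$l1 <- .l1_error(tt, C, Ct)
    proj$C <- C
    proj
  }

  # initializer: CG-mapped base from the constraints (auxiliary scale free;
  # chosen so the base damping matches the Langevin rate v2/D), replicated N
  # times with the ion coupling split across particles, then jittered and
  # projected until a stable constrained model appears.
  if (is.null(init_fp)) {
    eta1 <- unname(tgt["u2"] / tgt["v2"])
    z2 <- unname(tgt["u2"]^2 / tgt["v2"])
    eta2 <- unname((z2 / tgt["D"]) * (tgt["v2"] / tgt["u2"])^2)
    eta3 <- z2 / unname(tgt["u2"])
    eta4 <- sqrt(2 * eta2 * z2)
    base <- matrix(rep(c(eta1 / N, eta2, eta3, eta4 / eta1), each = N), N, 4)
  } else {
    stopifnot(inherits(init_fp, "fict_params"))
    base <- init_fp$alpha
  }
  cur <- NULL
  for (k in seq_len(init_tries)) {
    a <- base * exp(matrix(stats::rnorm(4 * N, 0, if (k == 1 && !is.null(init_fp)) 0 else 0.3),
                           N, 4))
    cur <- eval_prop(a)
    if (!is.null(cur)) break
  }
  if (is.null(cur))
    stop("no stable constraint-satisfying initializer found within budget")

  trace <- cur$l1
  accepted <- 1L
  consec <- 0L
  for (it in seq_len(max_iter)) {
    prop <- eval_prop(cur$alpha * exp(matrix(stats::rnorm(4 * N, 0, sigma), N, 4)))
    if (!is.null(prop) && prop$l1 < cur$l1) {
      cur <- prop
      trace <- c(trace, cur$l1)
      accepted <- accepted + 1L
      consec <- 0L
    } else {
      consec <- consec + 1L
      if (consec >= anneal_after) {
        sigma <- sigma / 2
        consec <- 0L
      }
    }
  }
  structure(list(params = fict_params(cur$alpha), trace = trace,
                 l1 = cur$l1, moments = cur$moments, constraints = tgt,
                 target = target, C = cur$C, accepted = accepted,
                 iterations = max_iter),
            class = "vacf_fit")
}

#' @export
print.vacf_fit <- function(x, ...) {
  span <- diff(range(x$target$t))
  cat(sprintf("VACF fit: N = %d, %d accepted / %d proposals\n",
              x$params$N, x$accepted, x$iterations))
  cat(sprintf("  L1 error = %.4g (%.2f%% of C(0) x span)\n",
              x$l1, 100 * x$l1 / (x$target$C[1] * span)))
  cat(sprintf("  constraints (D, v2, u2) = (%.4g, %.4g, %.4g), met to %.1e\n",
              x$constraints["D"], x$constraints["v2"], x$constraints["u2"],
              max(abs(x$moments[c("D", "v2", "u2")] /
                        x$constraints[c("D", "v2", "u2")] - 1))))
  invisible(x)
}

#' @export
coef.vacf_fit <- function(object, ...) object$params$alpha

#' @export
plot.vacf_fit <- function(x, ...) {
  plot(x$target$t, x$target$C, type = "l", col = "blue",
       xlab = "t [ps]", ylab = "C(t) [A^2/ps^2]", ...)
  graphics::lines(x$target$t, x$C, col = "red", lty = 2)
  graphics::legend("topright", c("target", "fit"), col = c("blue", "red"),
                   lty = c(1, 2), bty = "n")
  invisible(x)
}

#' Read and write fictitious-particle parameter files
#'
#' Plain-text table, one row per fictitious particle, header
#' `alpha1 alpha2 alpha3 alpha4`.
#'
#' @param fp a [fict_params()].
#' @param file path.
#' @return `read_fp_params()` returns a [fict_params()].
#' @export
write_fp_params <- function(fp, file) {
  stopifnot(inherits(fp, "fict_params"))
  utils::write.table(format(as.data.frame(fp$alpha), digits = 17),
                     file, quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_fp_params
#' @export
read_fp_params <- function(file) {
  d <- utils::read.table(file, header = TRUE)
  if (!all(paste0("alpha", 1:4) %in% names(d)))
    stop("malformed parameter file")
  fict_params(as.matrix(d[paste0("alpha", 1:4)]))
}
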