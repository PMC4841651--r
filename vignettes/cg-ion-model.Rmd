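---
title: "A stochastic coarse-grained ion model and its coupling to Brownian dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A stochastic coarse-grained ion model and its coupling to Brownian dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgion)
```

## The model

All-atom simulations of a single ion in explicit water resolve femtosecond
physics, but transport questions (how long does an ion take to travel
hundreds of angstroms?) live on nanosecond-and-beyond scales where only
Brownian dynamics (BD), `dX = sqrt(2D) dW`, is affordable. The two
descriptions cannot be glued together directly: BD is memoryless in
velocity, while the force on a real ion is strongly correlated from one
femtosecond to the next. Langevin dynamics, the usual intermediate, fails
here for a quantifiable reason: parametrized to the measured diffusion
constant and velocity variance, its discretized one-step acceleration has
second moment
$\langle V^2\rangle^3/D^2 + 2\langle V^2\rangle^2/(D\,\Delta t)$
(`langevin_moment_check()`), about $4.4\times 10^5$ A$^2$ ps$^{-4}$ for
K$^+$ at $\Delta t = 10^{-3}$ ps — two orders of magnitude larger than the
measured $\langle U^2\rangle \approx 4.9\times 10^3$.

The model in this package inserts one more derivative and an auxiliary
variable. Per spatial component $i$,

$$dX_i = V_i\,dt,\qquad dV_i = U_i\,dt,\qquad
  dU_i = (-\eta_1 V_i + Z_i)\,dt,\qquad
  dZ_i = -(\eta_2 Z_i + \eta_3 U_i)\,dt + \eta_4\,dW_i,$$

with four positive coefficients ($\eta_1, \eta_3$ in ps$^{-2}$, $\eta_2$ in
ps$^{-1}$, $\eta_4$ in A ps$^{-7/2}$). Position, velocity and acceleration
are physical; $Z$ carries the memory of the solvent forcing. The system is
linear, so everything of interest — stationary covariances, the velocity
autocorrelation function (VACF), second-moment dynamics — is available in
closed form, and that is what the package exploits throughout. Units are
fixed to angstroms, picoseconds and daltons everywhere; there is no unit
conversion layer.

## Parametrization

Four fine-scale observables pin down the four coefficients exactly
(`fit_cg_params()`): writing $v_2 = \langle V_i^2\rangle$,
$u_2 = \langle U_i^2\rangle$, $z_2 = \langle Z_i^2\rangle$ for the
stationary second moments and $D$ for the diffusion constant,

$$\eta_1 = u_2/v_2,\qquad \eta_3 = z_2/u_2,\qquad
  \eta_2 = \frac{z_2}{D}\Big(\frac{v_2}{u_2}\Big)^2,\qquad
  \eta_4 = \sqrt{2\eta_2 z_2}.$$

These follow from setting the stationary cross-moments
$\langle UV\rangle = \langle UZ\rangle = \langle VZ\rangle = 0$ in the
moment equations, plus the position identities $\langle XV\rangle = D$,
$\langle XU\rangle = -v_2$, $\langle XZ\rangle = \eta_1 D$. The map is a
bijection: `implied_stats()` inverts it in closed form, and the identity
$\eta_4/(\eta_1\eta_2) = \sqrt{2D}$ is what makes the model collapse to the
correct BD limit on long time scales. $z_2$ is not directly observable in a
fine-scale run; it is estimated from the one-step change of acceleration by
`estimate_z2()`,
$z_2 \approx \langle((U(t+\Delta t)-U(t))/\Delta t + \eta_1 V(t))^2\rangle$.

Four ions ship with the package (`builtin_ions()`): K$^+$, Na$^+$,
Ca$^{2+}$ and Cl$^-$, with their published fine-scale statistics and fitted
coefficients stored exactly as printed (4 significant figures). Because the
printed statistics are themselves rounded, refitting reproduces the printed
coefficients only to about 0.3%; tests therefore compare at 0.5% relative
tolerance. This is a limitation of the printed inputs, not of the
estimators, which are exact inverses of each other to machine precision.

```{r}
k <- builtin_ions("K+")
fit_cg_params(k$stats)
```

## Linear analysis

The $(V, U, Z)$ subsystem has drift matrix
$B = \bigl(\begin{smallmatrix}0&1&0\\-\eta_1&0&1\\0&-\eta_3&-\eta_2
\end{smallmatrix}\bigr)$ with characteristic polynomial
$\lambda^3 + \eta_2\lambda^2 + (\eta_1+\eta_3)\lambda + \eta_1\eta_2$;
positivity of the coefficients forces all eigenvalue real parts into
$(-\eta_2, 0)$, and for all four ions the spectrum is one fast real mode
plus a slower complex-conjugate pair (`build_drift()` checks both stability
and distinctness). The per-component second moments close into a linear
ten-dimensional ODE system (`integrate_moments10()`); freezing the velocity
variance at its stationary value reduces it to four position-moment ODEs
(`integrate_moments4_reduced()`).

Two numbers summarize how the model approaches free diffusion. For large
$t$, $\langle X^2\rangle(t) \approx 2D\,(t - t^*)$, and `msd_time_shift()`
reports $t^*$ for either moment system: positive when the ion starts from
rest (`full10`; the model must first build up velocity) and negative when
the auxiliary subsystem starts stationary (`reduced4`). These shifts are the
systematic error committed when a BD particle is handed to the CG model with
deterministic zero initialization, and they are $O(10^{-2})$ ps — invisible
at BD time scales. We evaluate the shift at $t = 1$ ps with a convergence
assertion against $t = 0.5$ ps; the slowest relaxation rate of any built-in
ion is $\approx 12.75$ ps$^{-1}$, so by 1 ps the transient is below
$10^{-5}$ of its initial size and the choice of evaluation time is
immaterial to well beyond the 2% test tolerance.

The analytic VACF is $C(t) = e_1^\top e^{Bt}(v_2, 0, 0)^\top$ (`vacf_cg()`),
with $C(0) = v_2$ and Green–Kubo integral $\int_0^\infty C = D$. We compute
it by scaling-and-squaring matrix exponentials rather than by the
eigenvector expansion: the two are identical for distinct spectra, but the
exponential route stays well-conditioned when perturbed parameter sets drift
toward degeneracy (the eigen-expansion survives in the test suite as an
independent cross-check).

```{r}
build_drift(k$params)
msd_time_shift(k$params, "full10")
msd_time_shift(k$params, "reduced4")
```

## Simulation: Euler–Maruyama and the exact propagator

`cg_step()`/`simulate_cg()` implement the explicit Euler–Maruyama scheme at
a caller-chosen timestep (default $10^{-3}$ ps, matching the fine-scale
timestep so the model can run in lockstep with a fine-scale engine). The
stepper is deliberately minimal, and it is the scheme used by the hybrid
coupling below. Its price is an $O(|\mathrm{Re}\,\lambda|\,dt)$ bias in the
stationary law: at $dt = 10^{-3}$ ps the fast variables of K$^+$ sit about
8% ($U$) and 10% ($Z$) above their continuous-time variances, with the bias
halving as $dt$ halves (this is measured in the test suite).

Because the model is linear it also admits an *exact* discrete-time sampler:
$y_{k+1} = e^{A\,dt}y_k + L\xi_k$ with $LL^\top$ the van-Loan one-step noise
covariance (`simulate_cg(..., method = "exact")`). Its stationary law is
exactly the continuous model's at any timestep. The surrogate fine-scale
generator (`generate_surrogate()`) uses this sampler by default, because its
contract is to emulate a fine-scale trajectory *with prescribed stationary
moments*, against which the estimation pipeline is validated. Noise is drawn
from R's RNG in a fixed (step, component) order in both schemes, so every
trajectory is bit-reproducible from its seed, and the compiled loops are
bit-identical to the R-level reference steppers.

## Hybrid CG/BD coupling and its experiments

The multiscale geometry (`region_decomposition()`) is a sequence of nested,
closed, origin-centred cubes: a fine-scale core $\Omega_1$ of side $L$
(default 24.83 A, the simulation-box side of the reference fine-scale
setup), a hand-shaking shell $\Omega_2$ of width $L/(2\omega)$, a CG shell
$\Omega_3$ (width $h_1 = L/20$), a CG/BD hand-shaking shell $\Omega_4$
(width $h_2 = L/10$) and the unbounded BD region $\Omega_5$. Boundary points
belong to the inner region (closed inner boxes). The attenuation rule for
ion–solvent forces when the ion is outside the core — evaluate the force at
distances inflated by $\omega\,\mathrm{dist}(X, \Omega_1)$ — is implemented
as pure geometry (`attenuated_distance_args()`); no solvent forces are
computed in this package.

The CG model runs in $\Omega_3\cup\Omega_4$ and BD (timestep
$\Delta T = 0.5$ ps) in $\Omega_4\cup\Omega_5$; in the overlap $\Omega_4$ a
particle keeps whichever description it arrived with. Switch detection is
post-step, with no interpolation to the crossing time: the BD step length
$\sqrt{2D\Delta T}\approx 0.43$ A is small against the shell widths, so the
overshoot is immaterial. On re-entry into $\Omega_3$ the auxiliary state is
re-initialized deterministically to zero (default) or drawn from the
stationary law (`init_policy = "stationary"`); zero initialization is the
protocol used in the validation experiments and costs exactly the $t^*_1$
shift discussed above.

Two experiments validate the coupling. `run_halfspace_experiment()` starts
half the particles at $(+h, 0, 0)$ under CG and half at $(-h, 0, 0)$ under
BD and compares the final $X_1$ histogram with the two-Gaussian Brownian
reference (`analytic_halfspace_density()`, mass-normalized so it integrates
to the particle count). Both the dynamics and the half-space switching rule
are componentwise independent and only the $X_1$ marginal is observed, so
the experiment simulates component 1 alone — an exact reduction, not an
approximation — which makes the published configuration ($10^4$ particles,
$10^3$ ps) run in about two minutes. `escape_time_experiment()` starts one
ion at the origin of the full five-region geometry and records first-passage
times $T(r)$ out to $r = 4L$; with the bundled surrogate standing in for the
fine-scale model the empirical mean is compared against the Brownian theory
$\langle T(r)\rangle = r^2/(6D)$ with standard deviation
$r^2/(3\sqrt{10}D)$ and the corresponding 95% interval for a 100-sample
mean (`escape_theory()`).

## The fictitious-particle hierarchy

The CG model is the $N = 1$ member of a family in which $N$ damped, noisy
particles are harmonically coupled to the ion (`fict_params()`,
`simulate_fp()`); in transformed coordinates the extended drift
$\tilde B$ is $(2N+1)$-dimensional (`build_extended()`), the stationary
covariance solves the Lyapunov equation
$\tilde B S + S\tilde B^\top = -\tilde b\tilde b^\top$
(`stationary_covariance()`, solved by Kronecker vectorization — the systems
are at most $\sim\!15$-dimensional), and the VACF and Green–Kubo diffusion
constant follow in closed form (`vacf_fp()`, `diffusion_fp()`). The
$N = 1$ equivalence $\eta_{1,2,3} = \alpha_{1,(1,2,3)}$,
$\eta_4 = \alpha_{1,1}\alpha_{1,4}$ is exact pathwise: under a shared seed
the two simulators produce bit-identical trajectories.

With $N > 1$ the extra parameters can shape the VACF at intermediate times
while the three moment constraints ($D$, $v_2$, $u_2$) stay pinned.
`fit_vacf()` implements a constrained acceptance–rejection search: all $4N$
coefficients are perturbed log-normally (initial scale 0.05, halved after 50
consecutive rejections), each proposal is projected back onto the constraint
manifold exactly, and it is accepted only if the $L^1$ error against the
target VACF (trapezoid rule on the target's grid) decreases — so the error
trace is non-increasing by construction and *every* accepted iterate
satisfies the constraints to $10^{-6}$ or better.

The projection deserves a note, because it was a genuinely open design
point. Two exact dials are obvious: rescaling all $\alpha_{j,4}$ jointly
scales $(D, v_2, u_2)$ by a common factor, and a global time-dilation
(scaling $\alpha_{j,1}, \alpha_{j,3}$ by $s^2$, $\alpha_{j,2}$ by $s$,
$\alpha_{j,4}$ by $s^{3/2}$) scales them by $(s, s^2, s^4)$. Dimensional
analysis shows these two can never fix the dimensionless invariant
$D^2 u_2/v_2^3$, so a third dial is required: we rescale all the couplings
$\alpha_{j,1}$ jointly, solving for the factor by 1-D root finding on that
invariant (for $N = 1$ this dial provably leaves $D$ untouched). The two
closed-form scalings then restore $v_2$, $u_2$ and — through the matched
invariant — $D$ exactly. The multi-particle
$\langle U^2\rangle$ is defined as the stationary variance of the physical
acceleration $\sum_j\tilde U_j$, read off the $\tilde U$-block of the
Lyapunov solution.

```{r}
fp <- builtin_fp("K+")   # published N = 3 fit for K+
fp_moments(fp)
```

## The surrogate generator, and what passing tests do not show

`generate_surrogate()` produces the "fine-scale" trajectories every
pipeline stage is exercised against: a stationary-initialized exact-sampler
run of a reference CG (or fictitious-particle) model at
$\Delta t = 10^{-3}$ ps. It emulates precisely those features of fine-scale
data that the method consumes — prescribed stationary second moments and
diffusion constant, the linear conditional jerk structure
$J(v, u) = -\eta_1 v$, and a Gaussian stationary law. It does *not* emulate
non-Gaussian force statistics, anharmonic memory, or any position-dependent
structure of a real solvent; recovery tests passing on surrogate data
therefore validate the estimators and the plumbing, not the physical
fidelity of the CG model to any particular fine-scale force field. The one
fine-scale observable the CG model is known not to reproduce — the shape of
the VACF at intermediate times — is exactly what the $N > 1$ fictitious
hierarchy is for.

`recover_params_pipeline()` chains the estimators end to end (moments after
a default 10% burn-in; $z_2$ from the jerk estimator; $D$ from a
least-squares fit to the time-averaged MSD over a default window of
[1, 5] ps, safely past all relaxation times; then the closed-form
parameter map) and attaches block-averaged standard errors (10 contiguous
blocks). Burn-in is exposed rather than fixed because the appropriate
equilibration discard depends on how the input trajectory was produced.

## Numerical choices and problem sizes

* Moment ODEs: `deSolve::lsoda`, rtol $10^{-10}$ — the coefficients span
  $10^2$–$10^5$, which is mildly stiff.
* Matrix exponentials: dense scaling-and-squaring (`Matrix::expm`); on
  uniform time grids one propagator is computed and reused recursively.
* Jerk map: default 40 uniform bins per axis spanning $\pm 4$ standard
  deviations of $V$ and $U$; unoccupied cells are excluded, the $J_1$
  profile reads the $u$-bin containing zero, and $J_2$ is the
  occupancy-weighted $u$-average.
* Stochastic test sizes were chosen to keep the full suite in the
  tens-of-minutes range on one CPU: moment-recovery runs use $2\times10^5$
  to $3\times10^5$ steps (5–10% tolerances), the jerk-linearity check
  $10^6$ steps, the half-space comparison $10^4$ particles over $10^3$ ps,
  and the escape experiment 100 realizations per ion out to $4L$. Each is
  the published configuration or a documented scale-down of it, with
  tolerances set by the Monte-Carlo error at that size, and every
  stochastic test fixes its seed.
* Degenerate inputs are errors, not warnings: non-positive statistics or
  coefficients, repeated drift eigenvalues (within tolerance), unstable
  extended drifts, non-monotone time grids, windows outside the trajectory
  span, trajectories too short for an estimator.

## Known limitations

* The exact-propagator sampler and all analytic layers rely on linearity;
  nothing here extends to state-dependent forcing.
* The escape experiment's pluggable fine-scale interface is an R-level
  callback and is only practical for small runs; the production path uses
  the built-in CG surrogate in compiled code.
* First-passage times are recorded at the end of the step that crosses the
  target radius, with no sub-step interpolation; at the default timesteps
  the induced bias is far below the Monte-Carlo error of 100 realizations.
* The acceptance–rejection fit is a local, greedy search; with $N \ge 2$
  the constraint manifold has flat directions, so recovered coefficient
  matrices are not unique even when the fitted VACF is excellent.
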