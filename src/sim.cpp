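#include <Rcpp.h>
using namespace Rcpp;

// Euler-Maruyama update of one component of the CG system, right-hand sides
// evaluated at the pre-step state.  Noise enters only the auxiliary variable.
static inline void cg_update(double &x, double &v, double &u, double &z,
                             const double *eta, double dt, double sq, double xi) {
  const double x0 = x, v0 = v, u0 = u, z0 = z;
  x = x0 + v0 * dt;
  v = v0 + u0 * dt;
  u = u0 + (-eta[0] * v0 + z0) * dt;
  z = z0 - (eta[1] * z0 + eta[2] * u0) * dt + eta[3] * sq * xi;
  (void)x0;
}

// [[Rcpp::export]]
NumericMatrix cpp_simulate_cg(NumericVector eta, NumericVector init,
                              double dt, int n_steps) {
  // init: c(X, V, U, Z) each length 3; returns (n_steps+1) x 13 matrix
  // with columns t, x1..x3, v1..v3, u1..u3, z1..z3.
  if (init.size() != 12) stop("init must have length 12");
  NumericMatrix out(n_steps + 1, 13);
  double x[3], v[3], u[3], z[3];
  const double e[4] = {eta[0], eta[1], eta[2], eta[3]};
  const double sq = std::sqrt(dt);
  for (int i = 0; i < 3; ++i) {
    x[i] = init[i]; v[i] = init[3 + i]; u[i] = init[6 + i]; z[i] = init[9 + i];
  }
  out(0, 0) = 0.0;
  for (int i = 0; i < 3; ++i) {
    out(0, 1 + i) = x[i]; out(0, 4 + i) = v[i];
    out(0, 7 + i) = u[i]; out(0, 10 + i) = z[i];
  }
  for (int k = 1; k <= n_steps; ++k) {
    for (int i = 0; i < 3; ++i) {
      double xi = norm_rand();
      cg_update(x[i], v[i], u[i], z[i], e, dt, sq, xi);
    }
    bool ok = true;
    for (int i = 0; i < 3; ++i)
      if (!std::isfinite(x[i]) || !std::isfinite(v[i]) ||
          !std::isfinite(u[i]) || !std::isfinite(z[i])) ok = false;
    if (!ok) stop("numerical blow-up at step %d", k);
    out(k, 0) = k * dt;
    for (int i = 0; i < 3; ++i) {
      out(k, 1 + i) = x[i]; out(k, 4 + i) = v[i];
      out(k, 7 + i) = u[i]; out(k, 10 + i) = z[i];
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_simulate_fp(NumericMatrix alpha, NumericVector init,
                     double dt, int n_steps) {
  // Fictitious-particle hierarchy in transformed coordinates
  // (X, V, Utilde_j, Ztilde_j).  init: c(X(3), V(3), Ut(N*3), Zt(N*3)) with
  // Ut/Zt stored particle-major (j varies slowest, component fastest).
  // Noise order per step: particle j, then component i (matches the CG
  // simulator draw order when N = 1).
  const int N = alpha.nrow();
  if (init.size() != 6 + 6 * N) stop("init has wrong length");
  const double sq = std::sqrt(dt);
  std::vector<double> x(3), v(3), ut(3 * N), zt(3 * N);
  for (int i = 0; i < 3; ++i) { x[i] = init[i]; v[i] = init[3 + i]; }
  for (int k = 0; k < 3 * N; ++k) { ut[k] = init[6 + k]; zt[k] = init[6 + 3 * N + k]; }
  NumericMatrix X(n_steps + 1, 3), V(n_steps + 1, 3), U(n_steps + 1, 3);
  NumericMatrix Ut(n_steps + 1, 3 * N), Zt(n_steps + 1, 3 * N);
  NumericVector tt(n_steps + 1);
  auto store = [&](int k) {
    tt[k] = k * dt;
    for (int i = 0; i < 3; ++i) {
      X(k, i) = x[i]; V(k, i) = v[i];
      double s = 0; for (int j = 0; j < N; ++j) s += ut[3 * j + i];
      U(k, i) = s;
    }
    for (int m = 0; m < 3 * N; ++m) { Ut(k, m) = ut[m]; Zt(k, m) = zt[m]; }
  };
  store(0);
  std::vector<double> xi(3 * N);
  for (int k = 1; k <= n_steps; ++k) {
    for (int m = 0; m < 3 * N; ++m) xi[m] = norm_rand();
    double x0[3], v0[3];
    for (int i = 0; i < 3; ++i) { x0[i] = x[i]; v0[i] = v[i]; }
    for (int i = 0; i < 3; ++i) {
      double s = 0; for (int j = 0; j < N; ++j) s += ut[3 * j + i];
      x[i] = x0[i] + v0[i] * dt;
      v[i] = v0[i] + s * dt;
    }
    for (int j = 0; j < N; ++j) {
      const double a1 = alpha(j, 0), a2 = alpha(j, 1),
                   a3 = alpha(j, 2), a4 = alpha(j, 3);
      for (int i = 0; i < 3; ++i) {
        const double u0 = ut[3 * j + i], z0 = zt[3 * j + i];
        ut[3 * j + i] = u0 + (z0 - a1 * v0[i]) * dt;
        zt[3 * j + i] = z0 - (a2 * z0 + a3 * u0) * dt + a1 * a4 * sq * xi[3 * j + i];
      }
    }
    bool ok = true;
    for (int i = 0; i < 3; ++i) if (!std::isfinite(v[i])) ok = false;
    for (int m = 0; m < 3 * N; ++m)
      if (!std::isfinite(ut[m]) || !std::isfinite(zt[m])) ok = false;
    if (!ok) stop("numerical blow-up at step %d", k);
    store(k);
  }
  return List::create(_["t"] = tt, _["X"] = X, _["V"] = V, _["U"] = U,
                      _["Ut"] = Ut, _["Zt"] = Zt);
}

// [[Rcpp::export]]
NumericVector cpp_halfspace(NumericVector eta, double D, double h,
                            double dt, double dT, double t_end,
                            NumericVector x0, IntegerVector tag0,
                            int init_policy, NumericVector stat_sd) {
  // Hybrid CG/BD half-space experiment along the first coordinate only.
  // The dynamics and the switching rule are componentwise independent, so the
  // X1 marginal of the 3-D experiment coincides with this 1-D simulation.
  // tag: 0 = CG (active while x > -h), 1 = BD (active while x < h).
  // init_policy: 0 = zero re-entry initialization, 1 = stationary draw.
  const int n = x0.size();
  NumericVector xf(n);
  const double e[4] = {eta[0], eta[1], eta[2], eta[3]};
  const double sq = std::sqrt(dt);
  for (int p = 0; p < n; ++p) {
    double x = x0[p], v = 0, u = 0, z = 0, t = 0;
    int tag = tag0[p];
    if (tag == 0 && init_policy == 1) {
      v = stat_sd[0] * norm_rand();
      u = stat_sd[1] * norm_rand();
      z = stat_sd[2] * norm_rand();
    }
    while (t < t_end - 1e-12) {
      if (tag == 0) {
        double xi = norm_rand();
        cg_update(x, v, u, z, e, dt, sq, xi);
        t += dt;
        if (x <= -h) tag = 1;           // entered the BD-only region
      } else {
        double step = std::min(dT, t_end - t);
        x += std::sqrt(2.0 * D * step) * norm_rand();
        t += step;
        if (x >= h) {                    // entered the CG-only region
          tag = 0;
          if (init_policy == 1) {
            v = stat_sd[0] * norm_rand();
            u = stat_sd[1] * norm_rand();
            z = stat_sd[2] * norm_rand();
          } else { v = 0; u = 0; z = 0; }
        }
      }
    }
    xf[p] = x;
    if (p % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return xf;
}

// [[Rcpp::export]]
List cpp_escape(NumericVector eta, double D, double dt, double dT,
                double cg_out, double bd_in, NumericVector r_grid,
                int n_real, double t_max, int init_policy,
                NumericVector stat_sd) {
  // First-passage experiment on nested boxes: CG model active while the ion
  // is inside the box of half-width cg_out (max-norm); BD outside.  A BD ion
  // re-enters the CG description when it reaches the box of half-width bd_in.
  // T(r) is recorded at the end of the step that first reaches Euclidean
  // distance r from the origin (no sub-step refinement).
  const int nr = r_grid.size();
  NumericMatrix T(n_real, nr);
  LogicalVector truncated(n_real);
  std::fill(T.begin(), T.end(), NA_REAL);
  const double e[4] = {eta[0], eta[1], eta[2], eta[3]};
  const double sq = std::sqrt(dt);
  const double rmax2 = r_grid[nr - 1] * r_grid[nr - 1];
  for (int p = 0; p < n_real; ++p) {
    double x[3] = {0, 0, 0}, v[3], u[3], z[3], t = 0;
    for (int i = 0; i < 3; ++i) {
      if (init_policy == 1) {
        v[i] = stat_sd[0] * norm_rand();
        u[i] = stat_sd[1] * norm_rand();
        z[i] = stat_sd[2] * norm_rand();
      } else { v[i] = u[i] = z[i] = 0; }
    }
    int tag = 0, k = 0;   // next r-grid index to record
    long iter = 0;
    while (k < nr) {
      if (t > t_max) { truncated[p] = true; break; }
      double amax = 0;
      if (tag == 0) {
        for (int i = 0; i < 3; ++i) {
          double xi = norm_rand();
          cg_update(x[i], v[i], u[i], z[i], e, dt, sq, xi);
          amax = std::max(amax, std::fabs(x[i]));
        }
        t += dt;
        if (amax > cg_out) tag = 1;
      } else {
        double s = std::sqrt(2.0 * D * dT);
        for (int i = 0; i < 3; ++i) {
          x[i] += s * norm_rand();
          amax = std::max(amax, std::fabs(x[i]));
        }
        t += dT;
        if (amax <= bd_in) {
          tag = 0;
          for (int i = 0; i < 3; ++i) {
            if (init_policy == 1) {
              v[i] = stat_sd[0] * norm_rand();
              u[i] = stat_sd[1] * norm_rand();
              z[i] = stat_sd[2] * norm_rand();
            } else { v[i] = u[i] = z[i] = 0; }
          }
        }
      }
      double r2 = x[0] * x[0] + x[1] * x[1] + x[2] * x[2];
      while (k < nr && r2 >= r_grid[k] * r_grid[k]) T(p, k++) = t;
      if (r2 >= rmax2) break;
      if ((++iter & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["T"] = T, _["truncated"] = truncated);
}

// [[Rcpp::export]]
NumericMatrix cpp_simulate_exact(NumericMatrix P, NumericMatrix L,
                                 NumericVector init, int n_steps) {
  // Exact Gaussian one-step recursion y_{k+1} = P y_k + L xi for a linear
  // SDE, run independently for the three spatial components.  init holds
  // the three stacked m-vectors; L is a (generally full) square root of the
  // one-step noise covariance.  Draw order: step, component, state index.
  const int m = P.nrow();
  if (init.size() != 3 * m) stop("init has wrong length");
  NumericMatrix out(n_steps + 1, 3 * m);
  std::vector<double> y(3 * m), ynew(m), xi(m);
  for (int k = 0; k < 3 * m; ++k) { y[k] = init[k]; out(0, k) = init[k]; }
  for (int k = 1; k <= n_steps; ++k) {
    for (int c = 0; c < 3; ++c) {
      for (int i = 0; i < m; ++i) xi[i] = norm_rand();
      for (int i = 0; i < m; ++i) {
        double s = 0;
        for (int j = 0; j < m; ++j) s += P(i, j) * y[c * m + j];
        for (int j = 0; j < m; ++j) s += L(i, j) * xi[j];
        ynew[i] = s;
      }
      for (int i = 0; i < m; ++i) y[c * m + i] = ynew[i];
    }
    for (int i = 0; i < 3 * m; ++i) {
      if (!std::isfinite(y[i])) stop("numerical blow-up at step %d", k);
      out(k, i) = y[i];
    }
    if ((k & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
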