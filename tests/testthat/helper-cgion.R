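rel_err <- function(x, ref) abs(x - ref) / abs(ref)

# published per-ion reference values used across tests (printed 4-s.f. tables)
TAB_STATS <- list(
  "K+"   = c(D = 0.183, v2 = 6.32,  u2 = 4.86e3, z2 = 1.65e7),
  "Na+"  = c(D = 0.128, v2 = 10.8,  u2 = 2.21e4, z2 = 8.88e7),
  "Ca2+" = c(D = 0.053, v2 = 6.18,  u2 = 1.87e4, z2 = 9.23e7),
  "Cl-"  = c(D = 0.177, v2 = 6.98,  u2 = 6.56e3, z2 = 2.97e7))
TAB_ETA <- list(
  "K+"   = c(768.7,   152.5, 3.393e3, 7.094e4),
  "Na+"  = c(2.044e3, 166.1, 4.020e3, 1.717e5),
  "Ca2+" = c(3.026e3, 190.2, 4.933e3, 1.874e5),
  "Cl-"  = c(940.0,   189.7, 4.524e3, 1.061e5))
TAB_EIG <- list(
  "K+"   = list(real = -127.0, cplx = complex(real = -12.75, imaginary = 27.58)),
  "Na+"  = list(real = -140.1, cplx = complex(real = -12.99, imaginary = 47.47)),
  "Ca2+" = list(real = -163.1, cplx = complex(real = -13.58, imaginary = 57.84)),
  "Cl-"  = list(real = -162.9, cplx = complex(real = -13.41, imaginary = 30.25)))
TAB_SHIFT <- list(
  "K+"   = c(t1 = 3.08e-2,  t2 = -9.39e-3),
  "Na+"  = c(t1 = 6.15e-3,  t2 = -2.35e-2),
  "Ca2+" = c(t1 = 1.47e-3,  t2 = -2.48e-2),
  "Cl-"  = c(t1 = 2.50e-2,  t2 = -1.13e-2))

# random positive CG parameter sets spanning the magnitude range of the ions
random_cg_params <- function(n, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    cg_params(exp(runif(1, log(50), log(5e3))),
              exp(runif(1, log(20), log(500))),
              exp(runif(1, log(50), log(1e4))),
              exp(runif(1, log(1e3), log(5e5)))))
}
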