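# Shared fixtures, built in code and cached per test session.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

median_model <- function() cached("median_model", median_patient_model())

# a dosimetry-grade simulation of the median patient at the cohort-mean
# administration, reused across tests
median_sim <- function() cached("median_sim", {
  simulate_pbpk(median_model(), administration(142, 5.6))
})

fast_solver <- function(t_end = 3e4)
  solver_settings(rtol = 1e-6, atol = 1e-10, t_end = t_end)

# quick fit spec for tests that exercise plumbing, not estimation quality
quick_spec <- function(...) fit_spec(n_starts = 1, ...)

# noise-free virtual patient
noisefree_patient <- function(seed) {
  vp <- sample_virtual_patient(seed)
  vp$noise <- c(tumor_1 = 0, tumor_2 = 0, kidneys = 0,
                salivary_glands = 0, total_body = 0)
  vp
}

# Independent brute-force oracle: one binding organ + serum + urine,
# integrated with classic RK4 at a fixed small step. Coded directly from the
# mass-balance equations, independently of the package solver.
reduced_oracle <- function(pars, amount, t_inf, times, h = 0.01) {
  # state: serum, vasc, int_free, bound, internal, catabolite, urine
  with(pars, {
    deriv <- function(x, inp) {
      Cs <- x[1] / Vs; Cv <- x[2] / Vv; Cf <- x[3] / Vf; Cc <- x[6] / Vs
      bind <- kon1000 * Cf * (Rtot - x[4]) - koff * x[4]
      c(inp + F * (Cv - Cs) - TER * Cs,
        F * (Cs - Cv) - PS * (Cv - Cf),
        PS * (Cv - Cf) - bind,
        bind - lint * x[4],
        lint * x[4] - lrel * x[5],
        lrel * x[5] - CLcat * Cc,
        TER * Cs + CLcat * Cc)
    }
    x <- numeric(7)
    t <- 0
    out <- matrix(NA_real_, length(times), 7)
    ti <- 1
    # integrate the infusion and post-infusion segments separately so the
    # zero-order input is constant within every RK4 step
    for (seg in list(c(0, t_inf, amount / t_inf), c(t_inf, max(times), 0))) {
      nstep <- ceiling((seg[2] - seg[1]) / h)
      for (i in seq_len(nstep)) {
        k1 <- deriv(x, seg[3])
        k2 <- deriv(x + h / 2 * k1, seg[3])
        k3 <- deriv(x + h / 2 * k2, seg[3])
        k4 <- deriv(x + h * k3, seg[3])
        x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
        t <- t + h
        while (ti <= length(times) && times[ti] <= t + 1e-9) {
          out[ti, ] <- x
          ti <- ti + 1
        }
      }
    }
    while (ti <= length(times)) { # guard against accumulated rounding in t
      out[ti, ] <- x
      ti <- ti + 1
    }
    out
  })
}

# build the matching one-organ package model by zeroing all other exchanges
reduced_package_model <- function(pars) {
  cfg <- default_config()
  m <- median_patient_model(config = cfg)
  org <- m$organs
  keep <- "kidneys"
  org$flow <- ifelse(org$name == keep, pars$F, 1e-12)
  org$ps <- ifelse(org$name == keep, pars$PS, 1e-12)
  org$vascular_ml <- ifelse(org$name == keep, pars$Vv, 1e-6)
  org$interstitial_ml <- ifelse(org$name == keep, pars$Vf, 1e-6)
  m$organs <- org
  m$rtot <- ifelse(org$name == keep, pars$Rtot, 0)
  m$lint <- ifelse(org$name == keep, pars$lint, 0)
  m$lrel <- ifelse(org$name == keep, pars$lrel, 0)
  m$serum_volume <- pars$Vs
  m$cl_renal <- pars$TER
  m$cl_cat <- pars$CLcat
  m$k_on <- pars$kon1000 / 1000
  m$k_off <- pars$koff
  m$fu <- 0
  m
}

# rates kept gentle (max eigenvalue ~1/min) so the fixed-step RK4 oracle is
# itself accurate to ~1e-10 at h = 0.005 min
reduced_pars <- list(Vs = 3000, F = 20, PS = 10, Vv = 20, Vf = 50,
                     Rtot = 5, kon1000 = 4.6, koff = 0.046, lint = 0.001,
                     lrel = 3e-4, TER = 60, CLcat = 60)
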