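#' Administration of the radiolabeled peptide
#'
#' @param amount total peptide amount in nmol (labeled + unlabeled).
#' @param activity injected activity in GBq.
#' @param infusion_duration infusion length in min (zero-order input;
#'   default 10 min, 0 means bolus).
#' @param config configuration list.
#' @return an object of class `"administration"` with the derived labeled
#'   fraction (activity / molar activity / amount).
#' @export
administration <- function(amount, activity,
                           infusion_duration = NULL,
                           config = default_config()) {
  infusion_duration <- infusion_duration %||%
    config$administration$infusion_duration_min
  if (amount <= 0) stop("validation error: amount must be > 0")
  if (activity < 0) stop("validation error: activity must be >= 0")
  lf <- activity / config$ligand$molar_activity_gbq_nmol / amount
  if (lf > 1)
    stop("validation error: labeled fraction > 1 (activity too high for amount)")
  structure(list(amount = amount, activity = activity,
                 infusion_duration = infusion_duration,
                 labeled_fraction = lf), class = "administration")
}

#' Solver settings
#'
#' Settings for the stiff (linearly implicit Rosenbrock) integrator and the
#' output grid: log-spaced points on `[0, t_end]` with a densified early
#' segment covering infusion and the fast distribution phase.
#'
#' @param rtol,atol relative/absolute (nmol) tolerances.
#' @param t_end end of the simulation grid in min (default 3e4).
#' @param grid_points number of log-spaced output points (>= 400 by default).
#' @param max_steps integration step budget.
#' @param config configuration list.
#' @return a list of class `"solver_settings"`.
#' @export
solver_settings <- function(rtol = NULL, atol = NULL, t_end = NULL,
                            grid_points = NULL, max_steps = NULL,
                            config = default_config()) {
  s <- config$solver
  structure(list(rtol = rtol %||% s$rtol, atol = atol %||% s$atol,
                 t_end = t_end %||% s$t_end_min,
                 grid_points = grid_points %||% s$grid_points,
                 max_steps = max_steps %||% s$max_steps),
            class = "solver_settings")
}

output_grid <- function(solver, t_inf = 10) {
  tend <- solver$t_end
  early <- seq(0, min(600, tend), by = 2.5)
  lg <- 10^seq(log10(max(1, t_inf / 10)), log10(tend),
               length.out = solver$grid_points)
  sort(unique(signif(c(0, early, lg, tend), 12)))
}

#' Simulate the PBPK model
#'
#' Integrates the compartmental system for one administration and returns the
#' molar time courses and the per-region fractions of injected activity
#' `a_i(t)`. Two modes are available: `"total"` integrates the total-ligand
#' system and recovers the labeled tracer exactly as
#' `labeled_fraction * exp(-lambda_phys * t) * total` (labeled and unlabeled
#' ligand share all rates, so the tracer factorizes); `"two_species"`
#' integrates labeled and unlabeled ligand explicitly, coupled by receptor
#' competition and physical decay.
#'
#' @param model a [build_model()] result.
#' @param admin an [administration()].
#' @param solver a [solver_settings()].
#' @param mode `"total"` (fast, default) or `"two_species"`.
#' @param output_times optional vector of output times (min), overrides the
#'   default grid.
#' @param lambda_phys_override optional physical decay constant (for tests;
#'   e.g. 0 disables decay).
#' @return an object of class `"pbpk_sim"` with elements `time` (min),
#'   `states` (matrix, time x state), `activity` (data.frame of per-region
#'   activity fractions incl. `total_body`, `excreted`, `remainder`),
#'   `amounts` (total molar content per region), and echoes of model/admin.
#' @export
simulate_pbpk <- function(model, admin, solver = solver_settings(),
                          mode = c("total", "two_species"),
                          output_times = NULL, lambda_phys_override = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "pbpk_model"), inherits(admin, "administration"))
  lambda <- lambda_phys_override %||% model$lambda_phys
  times <- output_times %||% output_grid(solver, admin$infusion_duration)
  if (any(diff(times) <= 0)) stop("validation error: non-monotone time grid")
  org <- model$organs
  t_inf <- admin$infusion_duration
  pars <- list(
    F = org$flow, PS = org$ps, Vv = org$vascular_ml, Vf = org$interstitial_ml,
    Rtot = model$rtot, lint = model$lint, lrel = model$lrel,
    psma = as.integer(org$psma),
    Vs = model$serum_volume, TER = model$cl_renal, fu = model$fu,
    CLcat = model$cl_cat, kon = model$k_on, koff = model$k_off,
    kidney = match("kidneys", org$name),
    inf_rate = if (t_inf > 0) admin$amount / t_inf else 0,
    t_inf = t_inf, lambda = lambda,
    lf = max(admin$labeled_fraction, 0),
    two_species = (mode == "two_species")
  )
  if (t_inf <= 0) pars$inf_rate <- admin$amount # flag for bolus handled in C++
  res <- .pbpk_integrate(pars, times, solver$rtol, solver$atol,
                         hmax = max(times) / 4, max_steps = solver$max_steps)
  states <- res$states
  m <- model$layout$m

  lay <- model$layout
  region_amount <- function(block) {
    out <- matrix(0, nrow(block), length(lay$region),
                  dimnames = list(NULL, names(lay$region)))
    for (j in seq_along(lay$region))
      out[, j] <- rowSums(block[, lay$region[[j]], drop = FALSE])
    out
  }
  if (mode == "total") {
    tot <- states[, seq_len(m), drop = FALSE]
    amt <- region_amount(tot)
    decay <- exp(-lambda * times)
    afrac <- sweep(amt, 1, decay / admin$amount, `*`)
    serum_a <- (tot[, lay$serum] + tot[, lay$catabolite]) * decay / admin$amount
    excreted <- tot[, lay$urine] * decay / admin$amount
    total_body <- rowSums(tot[, -lay$urine, drop = FALSE]) * decay / admin$amount
  } else {
    lab <- states[, seq_len(m), drop = FALSE]
    mlab <- admin$amount * admin$labeled_fraction
    if (mlab <= 0) stop("two_species mode needs a positive labeled fraction")
    amt <- region_amount(lab + states[, m + seq_len(m), drop = FALSE])
    alab <- region_amount(lab) / mlab
    afrac <- alab
    serum_a <- (lab[, lay$serum] + lab[, lay$catabolite]) / mlab
    excreted <- lab[, lay$urine] / mlab
    total_body <- rowSums(lab[, -lay$urine, drop = FALSE]) / mlab
  }
  tracked <- c("kidneys", "salivary_glands", "tumor_1", "tumor_2", "red_marrow")
  activity <- data.frame(time_min = times, afrac, serum = serum_a,
                         total_body = total_body, excreted = excreted,
                         remainder = total_body -
                           rowSums(afrac[, tracked, drop = FALSE]),
                         check.names = FALSE)
  structure(list(time = times, states = states, activity = activity,
                 amounts = data.frame(time_min = times, amt, check.names = FALSE),
                 mode = mode, admin = admin, lambda_phys = lambda,
                 model = model, nsteps = res$nsteps),
            class = "pbpk_sim")
}

#' @export
print.pbpk_sim <- function(x, ...) {
  cat(sprintf("<pbpk_sim> %s mode, %d time points to %.0f min, %d steps\n",
              x$mode, length(x$time), max(x$time), x$nsteps))
  invisible(x)
}

#' Activity fraction of a region
#'
#' Fraction of the injected activity in a simulated region, `a_i(t)`.
#' `"total_body"` sums all internal compartments (excluding excreted),
#' `"remainder"` is total body minus the explicitly tracked source regions
#' (kidneys, salivary glands, tumors, red marrow).
#'
#' @param sim a [simulate_pbpk()] result.
#' @param region region identifier.
#' @return data.frame with columns `time_min` and `value`.
#' @export
activity_fraction <- function(sim, region) {
  stopifnot(inherits(sim, "pbpk_sim"))
  if (!region %in% names(sim$activity)[-1])
    stop("lookup error: unknown region '", region, "'")
  data.frame(time_min = sim$time, value = sim$activity[[region]])
}

#' Time-integrated activity coefficient
#'
#' Numerical integral of an activity-fraction series over `[0, T]` (units:
#' min). Integration uses cubic-spline quadrature on the supplied grid.
#'
#' @param series data.frame with `time_min` and `value` (as returned by
#'   [activity_fraction()]), or a list with `time`/`value`.
#' @param T upper limit in min (default 3e4).
#' @return the coefficient, in min.
#' @export
tiac <- function(series, T = 3e4) {
  s <- as_series(series)
  if (any(diff(s$time) <= 0)) stop("validation error: non-monotone time grid")
  if (T > max(s$time) + 1e-9)
    stop("validation error: series not defined up to T")
  integrate_series(s$time, s$value, T)
}

as_series <- function(series) {
  if (is.data.frame(series)) {
    tm <- series[["time_min"]] %||% series[["time"]]
    list(time = tm, value = series[["value"]])
  } else list(time = series$time %||% series$time_min, value = series$value)
}

# composite Simpson quadrature on the (non-uniform) sample grid over [0, T]
integrate_series <- function(time, value, T) {
  keep <- time <= T + 1e-9
  tt <- time[keep]; vv <- value[keep]
  if (abs(tt[length(tt)] - T) > 1e-9) {
    vv <- c(vv, stats::approx(time, value, xout = T)$y)
    tt <- c(tt, T)
  }
  n <- length(tt)
  if (n < 2) return(0)
  if (n == 2) return((tt[2] - tt[1]) * (vv[1] + vv[2]) / 2)
  # integral of the quadratic through (x0,f0),(x1,f1),(x2,f2) over [xl, xr]
  qint <- function(x0, x1, x2, f0, f1, f2, xl, xr) {
    d1 <- (f1 - f0) / (x1 - x0)
    d2 <- ((f2 - f1) / (x2 - x1) - d1) / (x2 - x0)
    ul <- xl - x0; ur <- xr - x0; del <- x1 - x0
    f0 * (xr - xl) + d1 * (ur^2 - ul^2) / 2 +
      d2 * ((ur^3 - ul^3) / 3 - del * (ur^2 - ul^2) / 2)
  }
  h <- diff(tt)
  total <- 0
  for (i in seq_len(n - 1)) {
    trap <- h[i] * (vv[i] + vv[i + 1]) / 2
    acc <- 0; nq <- 0
    # quadratic corrections only where neighbour spacing is comparable;
    # otherwise (e.g. across near-discontinuities) fall back to trapezoid
    if (i > 1 && h[i - 1] / h[i] > 0.1 && h[i - 1] / h[i] < 10) {
      acc <- acc + qint(tt[i - 1], tt[i], tt[i + 1], vv[i - 1], vv[i],
                        vv[i + 1], tt[i], tt[i + 1])
      nq <- nq + 1
    }
    if (i < n - 1 && h[i + 1] / h[i] > 0.1 && h[i + 1] / h[i] < 10) {
      acc <- acc + qint(tt[i], tt[i + 1], tt[i + 2], vv[i], vv[i + 1],
                        vv[i + 2], tt[i], tt[i + 1])
      nq <- nq + 1
    }
    total <- total + if (nq > 0) acc / nq else trap
  }
  total
}
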