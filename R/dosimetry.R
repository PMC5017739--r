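#' S-value set
#'
#' Loads the Lu-177 S-values used for absorbed-dose rates: the sphere
#' self-S-value table (for salivary glands and tumor lesions, assumed
#' spherical), the reference kidney self S-value (scaled inversely with the
#' measured kidney mass; Lu-177 dose is electron-dominated) and the red-marrow
#' self/remainder reference values with their reference body weight. The
#' sphere table shipped with the package is a synthetic stand-in derived from
#' the Lu-177 mean local energy deposition (see the fixture header).
#'
#' @param config configuration list.
#' @param sphere_table optional path to a `mass_g,svalue` CSV overriding the
#'   shipped fixture.
#' @return a list of class `"svalue_set"`.
#' @export
svalue_set <- function(config = default_config(), sphere_table = NULL) {
  path <- sphere_table %||% system.file("extdata", config$svalues$sphere_table,
                                        package = "psmaplan", mustWork = TRUE)
  tab <- utils::read.csv(path, comment.char = "#")
  names(tab) <- c("mass_g", "svalue")
  if (any(diff(tab$svalue) >= 0))
    stop("validation error: sphere S-values must be strictly decreasing in mass")
  if (any(tab$svalue <= 0)) stop("validation error: S-values must be > 0")
  sv <- config$svalues
  structure(list(sphere = tab,
                 kidney_self_ref = sv$kidney_self_ref,
                 kidney_ref_mass_g = sv$kidney_ref_mass_g,
                 rm_rm_ref = sv$rm_rm_ref, rm_rem_ref = sv$rm_rem_ref,
                 ref_weight_kg = sv$ref_weight_kg),
            class = "svalue_set")
}

#' Sphere self S-value by log-log interpolation
#'
#' @param mass sphere mass in g (unit density); must lie inside the table
#'   range, no extrapolation.
#' @param set an [svalue_set()].
#' @return S-value in Gy/(GBq min).
#' @export
sphere_svalue <- function(mass, set = svalue_set()) {
  tab <- set$sphere
  if (any(mass < min(tab$mass_g)) || any(mass > max(tab$mass_g)))
    stop("range error: mass outside sphere S-value table (",
         min(tab$mass_g), "-", max(tab$mass_g), " g)")
  exp(stats::approx(log(tab$mass_g), log(tab$svalue), xout = log(mass))$y)
}

#' Kidney self S-value scaled to the measured organ mass
#'
#' @param mass_g measured kidney mass (= volume at unit density).
#' @param set an [svalue_set()].
#' @return S-value in Gy/(GBq min).
#' @export
kidney_svalue <- function(mass_g, set = svalue_set()) {
  if (mass_g <= 0) stop("validation error: mass must be > 0")
  set$kidney_self_ref * set$kidney_ref_mass_g / mass_g
}

#' Red-marrow S-values scaled to the patient
#'
#' The marrow self S-value scales inversely with body weight (marrow mass
#' assumed proportional to weight); the remainder-to-marrow value is corrected
#' by the same inverse-mass scaling of the remainder (the configured
#' Hindorf-type scheme).
#'
#' @param body_weight patient weight in kg.
#' @param set an [svalue_set()].
#' @return list with `rm_rm` and `rm_rem`, Gy/(GBq min).
#' @export
marrow_svalues <- function(body_weight, set = svalue_set()) {
  if (body_weight <= 0) stop("validation error: body weight must be > 0")
  list(rm_rm = set$rm_rm_ref * set$ref_weight_kg / body_weight,
       rm_rem = set$rm_rem_ref * set$ref_weight_kg / body_weight)
}

#' Absorbed dose rate of a region
#'
#' Self-dose only: `Ddot_i(t) = A_inj * a_i(t) * S_i<-i`.
#'
#' @param a activity-fraction series (data.frame `time_min`, `value`).
#' @param A_inj injected activity, GBq.
#' @param S self S-value, Gy/(GBq min).
#' @return data.frame `time_min`, `value` (Gy/min).
#' @export
dose_rate <- function(a, A_inj, S) {
  if (A_inj < 0) stop("validation error: A_inj must be >= 0")
  s <- as_series(a)
  data.frame(time_min = s$time, value = A_inj * s$value * S)
}

#' @rdname dose_rate
#' @param a_rm,a_rem red-marrow and remainder activity-fraction series.
#' @param S_rm_rm,S_rm_rem marrow self and remainder-to-marrow S-values.
#' @export
dose_rate_rm <- function(a_rm, a_rem, A_inj, S_rm_rm, S_rm_rem) {
  if (A_inj < 0) stop("validation error: A_inj must be >= 0")
  s1 <- as_series(a_rm); s2 <- as_series(a_rem)
  if (length(s1$time) != length(s2$time) || any(s1$time != s2$time))
    stop("validation error: marrow and remainder series on different grids")
  data.frame(time_min = s1$time,
             value = A_inj * (s1$value * S_rm_rm + s2$value * S_rm_rem))
}

#' Absorbed dose
#'
#' Numerical integral of the dose-rate series over `[0, T]`.
#'
#' @param rate dose-rate series (Gy/min).
#' @param T upper limit in min.
#' @return absorbed dose in Gy.
#' @export
absorbed_dose <- function(rate, T = 3e4) {
  s <- as_series(rate)
  integrate_series(s$time, s$value, T)
}

# exact piecewise-linear repair convolution:
#   k2 = integral_0^T f(t) * integral_0^t f(w) exp(-mu (t-w)) dw dt
# with f linear inside each grid interval; the inner integral y(t) solves
# y' = f - mu*y exactly per interval, the outer uses Simpson with the exact
# midpoint value.
repair_double_integral <- function(time, f, mu, T) {
  keep <- time <= T + 1e-9
  tt <- time[keep]; ff <- f[keep]
  if (abs(tt[length(tt)] - T) > 1e-9) {
    ff <- c(ff, stats::approx(time, f, xout = T)$y)
    tt <- c(tt, T)
  }
  n <- length(tt)
  if (n < 2) return(0)
  # advance y over [0, h] with f(t) = f0 + s*t:  y(h) = y0 E + q(h)
  adv <- function(y0, f0, s, h) {
    if (mu * h < 1e-8) { # series to avoid cancellation
      y0 * (1 - mu * h) + f0 * h + 0.5 * s * h^2 - 0.5 * mu * h^2 * f0
    } else {
      E <- exp(-mu * h)
      y0 * E + (f0 / mu) * (1 - E) + (s / mu) * (h - (1 - E) / mu)
    }
  }
  y <- 0
  k2 <- 0
  for (i in seq_len(n - 1)) {
    h <- tt[i + 1] - tt[i]
    if (h <= 0) next
    s <- (ff[i + 1] - ff[i]) / h
    ymid <- adv(y, ff[i], s, h / 2)
    ynew <- adv(y, ff[i], s, h)
    fmid <- ff[i] + s * h / 2
    k2 <- k2 + h / 6 * (ff[i] * y + 4 * fmid * ymid + ff[i + 1] * ynew)
    y <- ynew
  }
  k2
}

#' Lea-Catcheside dose-protraction factor
#'
#' `G = (2/D^2) * int_0^T Ddot(t) int_0^t Ddot(w) exp(-mu (t-w)) dw dt`
#' with a mono-exponential repair kernel of rate `mu`. G is dimensionless,
#' lies in `[0, 1]`, and is invariant under scaling of the dose-rate curve.
#'
#' @param rate dose-rate (or activity-fraction) series.
#' @param mu repair rate in 1/min (> 0).
#' @param T integration horizon in min.
#' @return G; `NA` with attribute `reason` when the total dose is zero.
#' @export
lea_catcheside <- function(rate, mu, T = 3e4) {
  if (mu <= 0) stop("validation error: mu must be > 0")
  s <- as_series(rate)
  D <- integrate_series(s$time, s$value, T)
  if (D <= 0) {
    out <- NA_real_
    attr(out, "reason") <- "zero dose"
    return(out)
  }
  k2 <- repair_double_integral(s$time, s$value, mu, T)
  min(max(2 * k2 / D^2, 0), 1)
}

#' Biologically effective dose
#'
#' `BED = D * (1 + G * D / (alpha/beta))`.
#'
#' @param D absorbed dose, Gy.
#' @param G Lea-Catcheside factor.
#' @param alpha_beta linear-quadratic ratio, Gy.
#' @return BED in Gy.
#' @export
bed <- function(D, G, alpha_beta) {
  if (any(alpha_beta <= 0)) stop("validation error: alpha_beta must be > 0")
  D * (1 + G * D / alpha_beta)
}

# per-region radiobiology lookup (tumor lesions share the tumor entry)
radiobiology <- function(region, config = default_config()) {
  key <- if (grepl("^tumor", region)) "tumor" else region
  ab <- config$radiobiology$alpha_beta[[key]]
  th <- config$radiobiology$repair_halftime_min[[key]]
  if (is.null(ab) || is.null(th))
    stop("configuration error: no radiobiology entry for '", region, "'")
  list(alpha_beta = ab, mu = log(2) / th)
}

#' Dose report for one administration
#'
#' Combines a kinetic simulation with the S-values into the per-region
#' time-integrated activity coefficients, absorbed doses, Lea-Catcheside
#' factors and BEDs. Kidneys, salivary glands and tumors use self-dose only;
#' red marrow adds the remainder cross-dose.
#'
#' @param sim a [simulate_pbpk()] result.
#' @param A_inj injected activity in GBq (defaults to the simulated
#'   administration).
#' @param svalues an [svalue_set()].
#' @param T integration horizon, min.
#' @param config configuration list.
#' @return data.frame of class `"dose_report"`: region, tiac_min, svalue,
#'   dose_gy, g_factor, bed_gy, alpha_beta.
#' @export
dose_report <- function(sim, A_inj = NULL, svalues = svalue_set(),
                        T = 3e4, config = default_config()) {
  A_inj <- A_inj %||% sim$admin$activity
  org <- sim$model$organs
  weight <- sim$model$physiology$body_weight
  msv <- marrow_svalues(weight, svalues)
  regions <- c("kidneys", "salivary_glands", "tumor_1", "tumor_2", "red_marrow")
  rows <- lapply(regions, function(rg) {
    a <- activity_fraction(sim, rg)
    ta <- tiac(a, T)
    rb <- radiobiology(rg, config)
    if (rg == "red_marrow") {
      rate <- dose_rate_rm(a, activity_fraction(sim, "remainder"), A_inj,
                           msv$rm_rm, msv$rm_rem)
      S <- msv$rm_rm
    } else {
      S <- if (rg == "kidneys")
        kidney_svalue(org$mass_g[org$name == "kidneys"], svalues)
      else sphere_svalue(org$mass_g[org$name == rg], svalues)
      rate <- dose_rate(a, A_inj, S)
    }
    D <- absorbed_dose(rate, T)
    G <- lea_catcheside(rate, rb$mu, T)
    data.frame(region = rg, tiac_min = ta, svalue = S, dose_gy = D,
               g_factor = as.numeric(G), bed_gy = bed(D, as.numeric(G), rb$alpha_beta),
               alpha_beta = rb$alpha_beta)
  })
  out <- do.call(rbind, rows)
  attr(out, "A_inj") <- A_inj
  attr(out, "T") <- T
  class(out) <- c("dose_report", "data.frame")
  out
}
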