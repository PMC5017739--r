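#' Time-activity dataset for one region
#'
#' @param region one of `tumor_1`, `tumor_2`, `salivary_glands`, `kidneys`,
#'   `total_body`.
#' @param times measurement times in min, strictly increasing, >= 4 points.
#' @param values measured fractions of injected activity in `[0, 1.2]`.
#' @param sd optional known fractional SDs (informational).
#' @return a data.frame of class `"time_activity_dataset"`.
#' @export
time_activity_dataset <- function(region, times, values, sd = NULL) {
  if (length(times) != length(values)) stop("times and values differ in length")
  if (length(times) < 4)
    stop("validation error: at least 4 time points per region required")
  if (any(diff(times) <= 0))
    stop("validation error: times must be strictly increasing")
  if (any(values < 0) || any(values > 1.2))
    stop("validation error: values must lie in [0, 1.2]")
  out <- data.frame(region = region, time_min = times, value = values)
  if (!is.null(sd)) out$sd <- sd
  class(out) <- c("time_activity_dataset", "data.frame")
  out
}

#' Patient record
#'
#' Per-patient descriptors needed to build the PBPK model and interpret the
#' measurements: body surface area (or weight), tubular extraction rate, the
#' measured volumes and the administered amount/activity.
#'
#' @param bsa body surface area, m^2.
#' @param ter tubular extraction rate, ml/min.
#' @param volumes named list: `kidneys`, `salivary_glands`, `tumor_1`,
#'   `tumor_2` volumes in ml.
#' @param amount administered peptide, nmol.
#' @param activity administered activity, GBq.
#' @param weight optional body weight, kg (else derived from `bsa`).
#' @return a list of class `"patient_record"`.
#' @export
patient_record <- function(bsa, ter, volumes, amount, activity, weight = NULL) {
  structure(list(bsa = bsa, weight = weight, ter = ter, volumes = volumes,
                 amount = amount, activity = activity),
            class = "patient_record")
}

#' Fit specification
#'
#' The default free parameters are the binding-site densities and release
#' rates of kidneys, salivary glands and both tumor lesions, the salivary
#' perfusion `f_SAL`, and one shared muscle-background fraction: 10 free
#' parameters. Fixed: `lambda_int`, `f_TU`, `k_on`, `k_off`.
#'
#' @param k_off dissociation rate selecting the candidate model (min^-1).
#' @param f_tu fixed tumor perfusion, ml/g/min.
#' @param n_starts number of seeded multistart candidates.
#' @param n_polish how many of the best-ranked candidates are polished with
#'   the full optimizer run.
#' @param config configuration list.
#' @param ... overrides for fitting controls (`max_outer`, `max_lm_iter`,
#'   `fd_step`, `rtol`, `atol`, `aic_variance_per_region`).
#' @return a list of class `"fit_spec"`.
#' @export
fit_spec <- function(k_off = NULL, f_tu = NULL, n_starts = NULL, n_polish = 1,
                     config = default_config(), ...) {
  fc <- utils::modifyList(config$fitting, list(...))
  b <- lapply(fc$bounds, unlist)
  free <- c("r_kidneys", "r_salivary", "r_tumor_1", "r_tumor_2",
            "lrel_kidneys", "lrel_salivary", "lrel_tumor_1", "lrel_tumor_2",
            "f_sal", "background")
  lower <- c(rep(b$density[1], 4), rep(b$release[1], 4), b$f_sal[1], b$background[1])
  upper <- c(rep(b$density[2], 4), rep(b$release[2], 4), b$f_sal[2], b$background[2])
  names(lower) <- names(upper) <- free
  if (any(lower <= 0)) stop("validation error: bounds must be positive")
  structure(list(
    free = free, lower = lower, upper = upper,
    k_off = k_off %||% config$ligand$k_off,
    f_tu = f_tu %||% config$physiology$tumor_1$perfusion,
    n_starts = n_starts %||% fc$n_starts, n_polish = n_polish,
    control = fc, config = config
  ), class = "fit_spec")
}

# default start: configuration medians
fit_start <- function(spec) {
  cfg <- spec$config
  c(r_kidneys = cfg$receptors$kidneys, r_salivary = cfg$receptors$salivary_glands,
    r_tumor_1 = cfg$receptors$tumor_1, r_tumor_2 = cfg$receptors$tumor_2,
    lrel_kidneys = cfg$ligand$lambda_release$kidneys,
    lrel_salivary = cfg$ligand$lambda_release$salivary_glands,
    lrel_tumor_1 = cfg$ligand$lambda_release$tumor_1,
    lrel_tumor_2 = cfg$ligand$lambda_release$tumor_2,
    f_sal = 0.16, background = cfg$background$fraction)
}

# model factory: natural parameter vector -> list(model, admin)
default_model_factory <- function(patient, spec) {
  cfg <- spec$config
  force(patient)
  function(theta) {
    phys <- physiology_set(bsa = patient$bsa, weight = patient$weight,
                           ter = patient$ter, volumes = patient$volumes,
                           f_sal = theta[["f_sal"]], f_tu = spec$f_tu,
                           config = cfg)
    rec <- receptor_map(kidneys = theta[["r_kidneys"]],
                        salivary_glands = theta[["r_salivary"]],
                        tumor_1 = theta[["r_tumor_1"]],
                        tumor_2 = theta[["r_tumor_2"]], config = cfg)
    lig <- ligand_params(k_off = spec$k_off,
                         lambda_release = list(
                           kidneys = theta[["lrel_kidneys"]],
                           salivary_glands = theta[["lrel_salivary"]],
                           tumor_1 = theta[["lrel_tumor_1"]],
                           tumor_2 = theta[["lrel_tumor_2"]]),
                         config = cfg)
    list(model = build_model(phys, rec, lig, config = cfg),
         admin = administration(patient$amount, patient$activity, config = cfg))
  }
}

#' Predicted ROI measurement series
#'
#' Planar ROI values are contaminated by over-/underlying tissue; the model
#' accounts for this by adding a fraction of the muscle-compartment signal:
#' `predicted(t) = a_region(t) + background_fraction * a_muscle(t)`. The
#' total-body ROI uses background 0.
#'
#' @param sim a [simulate_pbpk()] result.
#' @param region region identifier.
#' @param background_fraction non-negative scalar.
#' @return data.frame with `time_min` and `value`.
#' @export
predict_roi <- function(sim, region, background_fraction = 0) {
  if (background_fraction < 0)
    stop("validation error: background_fraction must be >= 0")
  if (region == "total_body") background_fraction <- 0
  a <- activity_fraction(sim, region)
  if (background_fraction > 0)
    a$value <- a$value + background_fraction * activity_fraction(sim, "muscle")$value
  a
}

# all predicted values for the datasets at parameter vector theta (natural)
fit_predict <- function(theta, datasets, factory, times_all, control) {
  fm <- factory(theta)
  solver <- solver_settings(rtol = control$rtol, atol = control$atol,
                            t_end = max(times_all))
  sim <- simulate_pbpk(fm$model, fm$admin, solver, output_times = times_all)
  unlist(lapply(datasets, function(d) {
    bg <- if (d$region[1] == "total_body") 0 else theta[["background"]]
    p <- predict_roi(sim, d$region[1], bg)
    p$value[match(d$time_min, p$time_min)]
  }), use.names = FALSE)
}

#' Fit patient-specific PBPK parameters
#'
#' Minimizes a relative-variance weighted least-squares objective: each
#' region's measurement variance is `phi_r * measurement^2` (relative error
#' model) with the proportionality constant `phi_r` profiled per region
#' (iteratively reweighted least squares around a Levenberg-Marquardt core on
#' log-transformed parameters). Standard errors and correlations come from
#' the Gauss-Newton curvature at the optimum.
#'
#' @param datasets list of [time_activity_dataset()]s (one per region).
#' @param spec a [fit_spec()].
#' @param patient a [patient_record()] (or `virtual_patient`).
#' @param model_factory optional custom factory `function(theta) ->
#'   list(model, admin)`; defaults to the whole-body model builder.
#' @param seed seed for the multistart perturbations.
#' @param start optional named start values (natural scale).
#' @return an object of class `"fit_result"`: `estimates`, `cv_pct`,
#'   `correlation`, `r2` and `fractional_sd` per region, `objective`
#'   (concentrated -2 log likelihood up to a constant), `aic`, `n_obs`,
#'   `k`, `at_bounds`, `converged`, `fitted` curves and the data.
#' @export
fit_patient <- function(datasets, spec = fit_spec(), patient,
                        model_factory = NULL, seed = 1, start = NULL) {
  if (inherits(datasets, "time_activity_dataset")) datasets <- list(datasets)
  for (d in datasets) stopifnot(inherits(d, "time_activity_dataset"))
  regions <- vapply(datasets, function(d) d$region[1], "")
  if (anyDuplicated(regions)) stop("duplicate region datasets")
  factory <- model_factory %||% default_model_factory(patient, spec)
  control <- spec$control
  times_all <- sort(unique(unlist(lapply(datasets, `[[`, "time_min"))))
  y <- unlist(lapply(datasets, `[[`, "value"), use.names = FALSE)
  ridx <- rep(seq_along(datasets), vapply(datasets, nrow, 0L))
  nr <- tabulate(ridx)

  lw <- log(spec$lower); up <- log(spec$upper)
  x0 <- log(pmin(pmax(start %||% fit_start(spec), spec$lower), spec$upper))
  x0 <- x0[spec$free]

  predict_x <- function(x) {
    fit_predict(stats::setNames(exp(x), spec$free), datasets, factory,
                times_all, control)
  }
  # candidate starts: configured start plus seeded log-normal perturbations
  starts <- list(x0)
  if (spec$n_starts > 1) {
    starts <- c(starts, withr::with_seed(seed, lapply(
      seq_len(spec$n_starts - 1), function(i)
        pmin(pmax(x0 + stats::rnorm(length(x0), 0, 0.7), lw), up))))
  }
  obj0 <- vapply(starts, function(x) {
    p <- tryCatch(predict_x(x), error = function(e) NULL)
    if (is.null(p)) return(Inf)
    sum(nr * log(pmax(rowsum((y - p)^2 / pmax(y, 1e-12)^2, ridx)[, 1], 1e-300) / nr))
  }, 0)
  ord <- order(obj0)[seq_len(min(spec$n_polish, sum(is.finite(obj0))))]
  if (!length(ord)) stop("fit error: no feasible start point")

  runs <- lapply(ord, function(i)
    irls_lm(starts[[i]], predict_x, y, ridx, nr, lw, up, control))
  objs <- vapply(runs, `[[`, 0, "objective")
  # lowest objective wins; ties broken by smaller parameter norm
  best <- runs[[order(objs, vapply(runs, function(r) sum(r$x^2), 0))[1]]]

  x <- best$x
  theta <- stats::setNames(exp(x), spec$free)
  p <- best$pred
  phi <- best$phi
  w <- sqrt(phi[ridx]) * pmax(y, 1e-12)
  # Gauss-Newton covariance on the log scale
  J <- fd_jacobian(function(z) (y - predict_x(z)) / w, x,
                   (y - p) / w, control$fd_step, lw, up)
  # residual degrees-of-freedom scale correction (weighted SSR / (n - k))
  s2 <- sum(((y - p) / w)^2) / max(length(y) - length(x), 1)
  cov <- tryCatch(solve(crossprod(J)) * s2, error = function(e)
    matrix(NA_real_, length(x), length(x)))
  se_log <- sqrt(pmax(diag(cov), 0))
  cv_pct <- 100 * sqrt(exp(se_log^2) - 1)        # delta method, natural scale
  corr <- cov / outer(se_log, se_log)
  diag(corr) <- 1
  dimnames(corr) <- list(spec$free, spec$free)

  ssr_rel <- rowsum((y - p)^2 / pmax(y, 1e-12)^2, ridx)[, 1]
  r2 <- vapply(seq_along(datasets), function(r) {
    yr <- y[ridx == r]; pr <- p[ridx == r]
    1 - sum((yr - pr)^2) / sum((yr - mean(yr))^2)
  }, 0)
  k <- length(spec$free) +
    if (isTRUE(control$aic_variance_per_region)) length(datasets) else 1L
  n <- length(y)
  objective <- sum(nr * log(ssr_rel / nr))
  at_bounds <- (x <= lw + 1e-6) | (x >= up - 1e-6)
  fitted <- do.call(rbind, lapply(seq_along(datasets), function(r)
    data.frame(region = regions[r], time_min = datasets[[r]]$time_min,
               observed = y[ridx == r], predicted = p[ridx == r])))

  structure(list(
    estimates = theta, cv_pct = stats::setNames(cv_pct, spec$free),
    correlation = corr,
    r2 = stats::setNames(r2, regions),
    fractional_sd = stats::setNames(sqrt(ssr_rel / nr), regions),
    objective = objective, aic = objective + 2 * k,
    n_obs = n, k = k, at_bounds = stats::setNames(at_bounds, spec$free),
    converged = best$converged, spec = spec, data = datasets,
    fitted = fitted, k_off = spec$k_off, f_tu = spec$f_tu
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %d obs, k=%d, objective %.3f, AIC %.2f%s\n",
              x$n_obs, x$k, x$objective, x$aic,
              if (x$converged) "" else " (NOT converged)"))
  est <- data.frame(estimate = signif(x$estimates, 4),
                    cv_pct = round(x$cv_pct, 1))
  print(est)
  cat("R^2 per region:", paste(sprintf("%s %.3f", names(x$r2), x$r2),
                               collapse = ", "), "\n")
  invisible(x)
}

# ---- optimizer internals -------------------------------------------------

fd_jacobian <- function(rfun, x, r0, h, lw, up) {
  J <- matrix(0, length(r0), length(x))
  for (j in seq_along(x)) {
    hj <- if (x[j] + h <= up[j]) h else -h
    xj <- x; xj[j] <- x[j] + hj
    J[, j] <- (rfun(xj) - r0) / hj
  }
  J
}

# iteratively reweighted least squares with an LM core; x on log scale
irls_lm <- function(x, predict_x, y, ridx, nr, lw, up, control) {
  p <- predict_x(x)
  den <- pmax(y, 1e-12)
  phi <- pmax(rowsum((y - p)^2 / den^2, ridx)[, 1] / nr, 1e-10)
  obj <- function(p) {
    ssr <- rowsum((y - p)^2 / den^2, ridx)[, 1]
    sum(nr * log(pmax(ssr, 1e-300) / nr))
  }
  f_prev <- obj(p)
  converged <- FALSE
  for (outer in seq_len(control$max_outer)) {
    w <- sqrt(phi[ridx]) * den
    rfun <- function(z) (y - predict_x(z)) / w
    lm <- lm_core(rfun, x, lw, up, control)
    x <- lm$x
    p <- predict_x(x)
    phi <- pmax(rowsum((y - p)^2 / den^2, ridx)[, 1] / nr, 1e-10)
    f_new <- obj(p)
    converged <- lm$converged
    if (abs(f_prev - f_new) < 1e-3 * (abs(f_prev) + 1)) {
      f_prev <- f_new
      break
    }
    f_prev <- f_new
  }
  list(x = x, pred = p, phi = phi, objective = f_prev, converged = converged)
}

lm_core <- function(rfun, x, lw, up, control) {
  r <- rfun(x)
  f <- sum(r^2)
  J <- fd_jacobian(rfun, x, r, control$fd_step, lw, up)
  age <- 0 # accepted steps since the last full finite-difference Jacobian
  lambda <- 1e-3
  converged <- FALSE
  for (it in seq_len(control$max_lm_iter)) {
    g <- crossprod(J, r)
    A <- crossprod(J)
    step <- tryCatch(
      solve(A + lambda * diag(pmax(diag(A), 1e-12), nrow(A)), -g),
      error = function(e) NULL)
    accepted <- FALSE
    if (!is.null(step)) {
      xn <- pmin(pmax(x + drop(step), lw), up)
      rn <- rfun(xn)
      fn <- sum(rn^2)
      accepted <- is.finite(fn) && fn < f
    }
    if (accepted) {
      # measurement noise sets the meaningful objective resolution
      small <- f - fn < 1e-5 * (f + 1e-3) || max(abs(xn - x)) < 1e-4
      ds <- xn - x
      if (age < 3 && sum(ds^2) > 0) { # cheap secant (Broyden) update
        J <- J + ((rn - r - J %*% ds) %*% t(ds)) / sum(ds^2)
        age <- age + 1
      } else {
        J <- fd_jacobian(rfun, xn, rn, control$fd_step, lw, up)
        age <- 0
      }
      x <- xn; r <- rn; f <- fn
      lambda <- max(lambda / 3, 1e-10)
      if (small) { converged <- TRUE; break }
    } else {
      lambda <- lambda * 4
      if (lambda > 1e7) {
        if (age > 0) { # the stale Jacobian may be the obstacle: refresh
          J <- fd_jacobian(rfun, x, r, control$fd_step, lw, up)
          age <- 0
          lambda <- 1e-2
        } else {
          converged <- TRUE # no descent with a fresh Jacobian: local optimum
          break
        }
      }
    }
  }
  list(x = x, converged = converged)
}

#' Akaike model comparison
#'
#' AIC per fit is `objective + 2k` where the objective is the concentrated
#' -2 log-likelihood term `sum_r n_r log(SSR_rel,r / n_r)` and `k` counts the
#' free parameters plus estimated variances (one per region by default).
#' Akaike weights are `w_m = exp(-Delta_m/2) / sum exp(-Delta/2)`. With
#' `correct = TRUE` the small-sample AICc penalty `2k(k+1)/(n-k-1)` is added.
#'
#' @param fits list of [fit_patient()] results on identical data.
#' @param correct apply the AICc small-sample correction.
#' @return data.frame with `aic`, `delta` and `weight` per fit.
#' @export
aic_compare <- function(fits, correct = FALSE) {
  if (length(fits) < 2) stop("need at least two fits")
  n <- vapply(fits, `[[`, 0, "n_obs")
  if (length(unique(n)) != 1)
    stop("validation error: fits were made on different data")
  sig <- function(f) vapply(f$data, function(d)
    paste(signif(c(d$time_min, d$value), 12), collapse = ","), "")
  s1 <- sig(fits[[1]])
  for (f in fits[-1])
    if (!identical(sig(f), s1))
      stop("validation error: fits were made on different data")
  aic <- vapply(fits, `[[`, 0, "aic")
  if (correct) {
    k <- vapply(fits, `[[`, 0, "k")
    aic <- aic + 2 * k * (k + 1) / pmax(n - k - 1, 1)
  }
  d <- aic - min(aic)
  w <- exp(-d / 2)
  data.frame(model = seq_along(fits),
             k_off = vapply(fits, function(f) f$k_off %||% NA_real_, 0),
             aic = aic, delta = d, weight = w / sum(w))
}
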