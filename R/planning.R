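#' Constraint set for treatment planning
#'
#' Per-cycle maximal tolerable doses assuming `n_cycles` cycles with equal
#' biodistribution: kidney BED (alpha/beta 2.5 Gy), salivary-gland absorbed
#' dose, red-marrow BED (alpha/beta 15 Gy). Defaults correspond to cumulative
#' limits of 40 / 30 / 1 Gy over 4 cycles.
#'
#' @param kidney_bed_max,salivary_dose_max,marrow_bed_max per-cycle limits, Gy.
#' @param n_cycles planned number of cycles.
#' @param config configuration list.
#' @return list of class `"constraint_set"`.
#' @export
constraint_set <- function(kidney_bed_max = NULL, salivary_dose_max = NULL,
                           marrow_bed_max = NULL, n_cycles = NULL,
                           config = default_config()) {
  cc <- config$constraints
  out <- structure(list(kidney_bed_max = kidney_bed_max %||% cc$kidney_bed_max,
                        salivary_dose_max = salivary_dose_max %||% cc$salivary_dose_max,
                        marrow_bed_max = marrow_bed_max %||% cc$marrow_bed_max,
                        n_cycles = n_cycles %||% cc$n_cycles),
                   class = "constraint_set")
  if (any(unlist(out) <= 0)) stop("validation error: constraints must be > 0")
  out
}

#' Activity that reaches a fixed kidney BED
#'
#' Closed-form inversion of `BED_K(A_inj) = bed_fixed`: with the
#' time-integrated activity coefficient `ã_K` and the repair-weighted double
#' integral `k2 = int_0^T a(t) int_0^t a(w) e^{-mu (t-w)} dw dt`, the BED is
#' quadratic in the injected activity and the positive root is
#' `A = alpha_beta * (-ã + sqrt(ã^2 + 8 k2 bed_fixed / alpha_beta)) / (4 S k2)`.
#'
#' @param a_k kidney activity-fraction series for the peptide amount of
#'   interest.
#' @param S_k kidney self S-value, Gy/(GBq min).
#' @param alpha_beta kidney linear-quadratic ratio, Gy.
#' @param mu kidney repair rate, 1/min.
#' @param bed_fixed target BED, Gy.
#' @param T integration horizon, min.
#' @return activity in GBq.
#' @export
activity_for_kidney_bed <- function(a_k, S_k, alpha_beta, mu, bed_fixed,
                                    T = 3e4) {
  if (bed_fixed <= 0) stop("validation error: bed_fixed must be > 0")
  s <- as_series(a_k)
  ta <- integrate_series(s$time, s$value, T)
  k2 <- repair_double_integral(s$time, s$value, mu, T)
  disc <- ta^2 + 8 * k2 * bed_fixed / alpha_beta
  if (disc <= 0 || k2 <= 0 || ta <= 0)
    stop("numerical error: degenerate kidney kinetics in BED inversion")
  alpha_beta * (-ta + sqrt(disc)) / (4 * S_k * k2)
}

#' Activity that reaches a fixed salivary-gland absorbed dose
#'
#' `A = D_fixed / (ã_SAL * S_SAL)`.
#'
#' @param tiac_sal salivary time-integrated activity coefficient, min.
#' @param S_sal salivary self S-value, Gy/(GBq min).
#' @param d_fixed target absorbed dose, Gy.
#' @return activity in GBq.
#' @export
activity_for_salivary_dose <- function(tiac_sal, S_sal, d_fixed) {
  if (tiac_sal <= 0)
    stop("division error: salivary time-integrated activity coefficient is zero")
  d_fixed / (tiac_sal * S_sal)
}

# kinetic kernels per region needed by the constraint inversions
region_kernels <- function(sim, T, config) {
  regions <- c("kidneys", "salivary_glands", "tumor_1", "tumor_2",
               "red_marrow", "remainder")
  out <- lapply(regions, function(rg) {
    a <- activity_fraction(sim, rg)
    mu <- if (rg == "remainder") NULL else radiobiology(
      if (rg == "red_marrow") "red_marrow" else rg, config)$mu
    list(tiac = integrate_series(a$time_min, a$value, T),
         k2 = if (is.null(mu)) NA_real_ else
           repair_double_integral(a$time_min, a$value, mu, T),
         a = a)
  })
  names(out) <- regions
  out
}

#' Build the planning grid over peptide amounts
#'
#' For every amount on the grid the kinetics are simulated once (activity
#' fractions depend on the amount but not on the activity), the case-1
#' (kidney BED limit) and case-2 (salivary absorbed-dose limit) activities are
#' computed, and all organ/tumor absorbed doses and BEDs at those activities
#' are tabulated together with the red-marrow feasibility flag.
#'
#' @param model a `pbpk_model` (amount-independent patient model).
#' @param constraints a [constraint_set()].
#' @param amounts peptide amounts in nmol (default `2^(1:13)`).
#' @param svalues an [svalue_set()].
#' @param solver a [solver_settings()].
#' @param T integration horizon, min.
#' @param config configuration list.
#' @return data.frame of class `"planning_grid"`, one row per amount and case.
#' @export
build_planning_grid <- function(model, constraints = constraint_set(),
                                amounts = 2^(1:13), svalues = svalue_set(),
                                solver = solver_settings(), T = 3e4,
                                config = default_config()) {
  org <- model$organs
  S_k <- kidney_svalue(org$mass_g[org$name == "kidneys"], svalues)
  S_sal <- sphere_svalue(org$mass_g[org$name == "salivary_glands"], svalues)
  S_tu1 <- sphere_svalue(org$mass_g[org$name == "tumor_1"], svalues)
  S_tu2 <- sphere_svalue(org$mass_g[org$name == "tumor_2"], svalues)
  msv <- marrow_svalues(model$physiology$body_weight, svalues)
  rb <- list(kidneys = radiobiology("kidneys", config),
             salivary_glands = radiobiology("salivary_glands", config),
             tumor_1 = radiobiology("tumor_1", config),
             tumor_2 = radiobiology("tumor_2", config),
             red_marrow = radiobiology("red_marrow", config))

  rows <- lapply(amounts, function(amt) {
    sim <- tryCatch(
      simulate_pbpk(model, administration(amt, 0, config = config), solver),
      error = function(e) stop("simulation failed at amount ", amt, " nmol: ",
                               conditionMessage(e)))
    kk <- region_kernels(sim, T, config)
    A1 <- activity_for_kidney_bed(kk$kidneys$a, S_k, rb$kidneys$alpha_beta,
                                  rb$kidneys$mu, constraints$kidney_bed_max, T)
    A2 <- activity_for_salivary_dose(kk$salivary_glands$tiac, S_sal,
                                     constraints$salivary_dose_max)
    one_case <- function(case, A) {
      d <- function(rg, S) A * kk[[rg]]$tiac * S
      g <- function(rg) {
        ta <- kk[[rg]]$tiac
        if (ta <= 0) return(0)
        min(max(2 * kk[[rg]]$k2 / ta^2, 0), 1)
      }
      d_rm <- A * (kk$red_marrow$tiac * msv$rm_rm + kk$remainder$tiac * msv$rm_rem)
      # marrow G from the combined self+remainder rate curve
      rate_rm <- kk$red_marrow$a$value * msv$rm_rm + kk$remainder$a$value * msv$rm_rem
      g_rm <- {
        k2 <- repair_double_integral(kk$red_marrow$a$time_min, rate_rm,
                                     rb$red_marrow$mu, T)
        dd <- integrate_series(kk$red_marrow$a$time_min, rate_rm, T)
        if (dd > 0) min(max(2 * k2 / dd^2, 0), 1) else 0
      }
      bed_rm <- bed(d_rm, g_rm, rb$red_marrow$alpha_beta)
      data.frame(
        amount_nmol = amt, case = case, activity_gbq = A,
        kidney_dose_gy = d("kidneys", S_k),
        kidney_bed_gy = bed(d("kidneys", S_k), g("kidneys"), rb$kidneys$alpha_beta),
        salivary_dose_gy = d("salivary_glands", S_sal),
        salivary_bed_gy = bed(d("salivary_glands", S_sal), g("salivary_glands"),
                              rb$salivary_glands$alpha_beta),
        tumor_1_dose_gy = d("tumor_1", S_tu1),
        tumor_1_bed_gy = bed(d("tumor_1", S_tu1), g("tumor_1"), rb$tumor_1$alpha_beta),
        tumor_2_dose_gy = d("tumor_2", S_tu2),
        tumor_2_bed_gy = bed(d("tumor_2", S_tu2), g("tumor_2"), rb$tumor_2$alpha_beta),
        marrow_bed_gy = bed_rm,
        marrow_ok = bed_rm <= constraints$marrow_bed_max)
    }
    rbind(one_case("kidney", A1), one_case("salivary", A2))
  })
  out <- do.call(rbind, rows)
  attr(out, "constraints") <- constraints
  class(out) <- c("planning_grid", "data.frame")
  out
}

#' Select the tumor-BED-optimal amount and activity
#'
#' Single-case mode maximizes the tumor BED along one iso-constraint curve
#' (kidney- or salivary-limited) after excluding red-marrow violations.
#' Combined mode takes, per amount on the comparison subgrid, the activity
#' satisfying both constraints (the row-wise minimum of the case activities),
#' excludes marrow violations and maximizes tumor BED. Ties are broken toward
#' the smaller amount.
#'
#' @param grid a [build_planning_grid()] result.
#' @param case `"kidney"`, `"salivary"` or `"combined"`.
#' @param tumor which lesion's BED to maximize (`"tumor_1"`/`"tumor_2"`).
#' @param subgrid amount range (nmol) used in combined mode (default
#'   `c(32, 512)`, i.e. 2^5-2^9).
#' @return list of class `"plan_recommendation"`: `feasible`, `amount_nmol`,
#'   `activity_gbq`, `tumor_dose_gy`, `tumor_bed_gy`, `case`, and the
#'   candidate `rows`.
#' @export
select_optimal <- function(grid, case = c("kidney", "salivary", "combined"),
                           tumor = "tumor_1", subgrid = c(32, 512)) {
  case <- match.arg(case)
  bedcol <- paste0(tumor, "_bed_gy")
  dosecol <- paste0(tumor, "_dose_gy")
  if (case %in% c("kidney", "salivary")) {
    cand <- grid[grid$case == case & grid$marrow_ok, , drop = FALSE]
  } else {
    g <- grid[grid$amount_nmol >= subgrid[1] & grid$amount_nmol <= subgrid[2], ,
              drop = FALSE]
    cand <- do.call(rbind, lapply(split(g, g$amount_nmol), function(rows) {
      rows[which.min(rows$activity_gbq), , drop = FALSE]
    }))
    if (nrow(cand)) {
      # at the binding (minimum) activity both constraints hold; recompute
      # feasibility flag from the stored marrow BED of that row
      cand <- cand[cand$marrow_ok, , drop = FALSE]
    }
  }
  if (!nrow(cand)) {
    return(structure(list(feasible = FALSE, case = case, tumor = tumor,
                          rows = cand), class = "plan_recommendation"))
  }
  ord <- order(-cand[[bedcol]], cand$amount_nmol)
  top <- cand[ord[1], ]
  structure(list(feasible = TRUE, case = case, tumor = tumor,
                 amount_nmol = top$amount_nmol, activity_gbq = top$activity_gbq,
                 tumor_dose_gy = top[[dosecol]], tumor_bed_gy = top[[bedcol]],
                 rows = cand), class = "plan_recommendation")
}

#' @export
print.plan_recommendation <- function(x, ...) {
  if (!x$feasible) {
    cat("<plan_recommendation> infeasible (all combinations violate a limit)\n")
    return(invisible(x))
  }
  cat(sprintf("<plan_recommendation> %s case, %s: %g nmol (%.0f ug), %.2f GBq -> D %.1f Gy, BED %.1f Gy\n",
              x$case, x$tumor, x$amount_nmol, x$amount_nmol * 1.66,
              x$activity_gbq, x$tumor_dose_gy, x$tumor_bed_gy))
  invisible(x)
}

#' Compare the actually administered protocol with the optimum
#'
#' The "actual" tumor dose uses the actually administered amount with the
#' activity that exhausts whichever constraint binds first (the minimum of the
#' kidney- and salivary-limited activities). The optimum is selected in
#' combined mode on the comparison subgrid. Returns the dose and BED ratios
#' (optimal / actual) per lesion.
#'
#' @param model patient `pbpk_model`.
#' @param actual_amount administered amount, nmol.
#' @param constraints a [constraint_set()].
#' @param subgrid comparison amounts, nmol (default `2^(5:9)`).
#' @param tumor lesion to optimize.
#' @param svalues,solver,T,config as in [build_planning_grid()].
#' @return list of class `"plan_comparison"`.
#' @export
compare_actual_vs_optimal <- function(model, actual_amount,
                                      constraints = constraint_set(),
                                      subgrid = 2^(5:9), tumor = "tumor_1",
                                      svalues = svalue_set(),
                                      solver = solver_settings(), T = 3e4,
                                      config = default_config()) {
  grid <- build_planning_grid(model, constraints,
                              amounts = sort(unique(c(subgrid, actual_amount))),
                              svalues = svalues, solver = solver, T = T,
                              config = config)
  opt <- select_optimal(grid, "combined", tumor = tumor,
                        subgrid = range(subgrid))
  act_rows <- grid[grid$amount_nmol == actual_amount, ]
  act <- act_rows[which.min(act_rows$activity_gbq), ]
  bedcol <- paste0(tumor, "_bed_gy"); dosecol <- paste0(tumor, "_dose_gy")
  structure(list(
    actual = list(amount_nmol = actual_amount,
                  activity_gbq = act$activity_gbq,
                  tumor_dose_gy = act[[dosecol]], tumor_bed_gy = act[[bedcol]],
                  marrow_ok = act$marrow_ok),
    optimal = opt,
    dose_ratio = if (opt$feasible) opt$tumor_dose_gy / act[[dosecol]] else NA_real_,
    bed_ratio = if (opt$feasible) opt$tumor_bed_gy / act[[bedcol]] else NA_real_,
    grid = grid, tumor = tumor
  ), class = "plan_comparison")
}

#' Akaike-weighted average of candidate tumor perfusion rates
#'
#' @param weights Akaike weights of the candidate rates (summing to ~1).
#' @param rates candidate perfusion rates, ml/g/min.
#' @param exclude_below weights below this threshold are dropped and the
#'   remaining weights renormalized (default 1%).
#' @return weighted mean rate, ml/g/min.
#' @export
weighted_perfusion <- function(weights, rates, exclude_below = 0.01) {
  if (length(weights) != length(rates)) stop("weights/rates length mismatch")
  keep <- weights >= exclude_below
  if (!any(keep)) stop("validation error: all rates excluded")
  sum(weights[keep] * rates[keep]) / sum(weights[keep])
}

#' Tumor-perfusion sensitivity analysis
#'
#' Tumor perfusion cannot be estimated together with the binding-site density
#' (they are strongly correlated), so it is fixed during fitting. This
#' analysis refits the patient with each candidate perfusion rate, compares
#' the fits by Akaike weights, reports the weight-averaged perfusion over the
#' supported rates (weight >= `exclude_below`), and optionally builds the
#' planning grid for each supported rate.
#'
#' @param datasets list of [time_activity_dataset()]s.
#' @param patient a [patient_record()].
#' @param rates candidate perfusion rates, ml/g/min.
#' @param spec base [fit_spec()] (its `f_tu` is overridden per rate).
#' @param exclude_below Akaike-weight threshold for exclusion.
#' @param plan build planning grids for supported rates.
#' @param seed multistart seed.
#' @param correct use AICc.
#' @param ... forwarded to [build_planning_grid()].
#' @return list of class `"perfusion_sensitivity"`: `fits`, `weights` (data
#'   frame rate/weight), `avg_rate`, optional `grids`.
#' @export
perfusion_sensitivity <- function(datasets, patient,
                                  rates = c(0.01, 0.1, 0.5, 1),
                                  spec = fit_spec(), exclude_below = 0.01,
                                  plan = FALSE, seed = 1, correct = FALSE, ...) {
  fits <- lapply(rates, function(r) {
    sp <- spec
    sp$f_tu <- r
    fit_patient(datasets, sp, patient, seed = seed)
  })
  cmp <- aic_compare(fits, correct = correct)
  w <- cmp$weight
  avg <- weighted_perfusion(w, rates, exclude_below)
  grids <- NULL
  if (plan) {
    keep <- which(w >= exclude_below)
    grids <- lapply(keep, function(i) {
      sp <- fit_spec(f_tu = rates[i])
      fm <- default_model_factory(patient, sp)(fits[[i]]$estimates)
      build_planning_grid(fm$model, ...)
    })
    names(grids) <- rates[keep]
  }
  structure(list(fits = fits,
                 weights = data.frame(rate = rates, weight = w,
                                      supported = w >= exclude_below),
                 avg_rate = avg, grids = grids),
            class = "perfusion_sensitivity")
}
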