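#' Cohort summary table
#'
#' Per-column mean and sample SD (n-1 denominator) of numeric patient
#' descriptors, rounded per the column display convention (integers for
#' amounts/volumes/TER/age, one decimal for GBq and m^2).
#'
#' @param records data.frame, one row per patient.
#' @param digits optional named integer vector of decimal places per column;
#'   defaults by column name.
#' @return data.frame with rows `mean` and `sd`.
#' @export
summarize_cohort <- function(records, digits = NULL) {
  if (!nrow(records)) stop("validation error: empty cohort")
  num <- records[vapply(records, is.numeric, TRUE)]
  default_digits <- function(nm) {
    if (grepl("gbq|bsa", nm, ignore.case = TRUE)) 1L else 0L
  }
  dg <- vapply(names(num), function(nm)
    if (!is.null(digits) && nm %in% names(digits)) digits[[nm]]
    else default_digits(nm), 0L)
  m <- vapply(num, mean, 0)
  s <- if (nrow(num) > 1) vapply(num, stats::sd, 0) else rep(NA_real_, ncol(num))
  out <- rbind(mean = mapply(function(v, d) round(v, d), m, dg),
               sd = mapply(function(v, d) round(v, d), s, dg))
  as.data.frame(out)
}

#' Assemble a run report
#'
#' Bundles the configuration echo (for provenance), fit summaries, dose
#' reports, planning grid and recommendation into one structure that
#' [render_report()] can serialize.
#'
#' @param config configuration list used for the run.
#' @param fits named list of `fit_result`s (optional).
#' @param doses named list of `dose_report`s (optional).
#' @param planning `planning_grid` (optional).
#' @param recommendation `plan_recommendation` (optional).
#' @param seed seed used for the run.
#' @param warnings character vector of warnings to surface.
#' @return list of class `"run_report"` (schema version 1).
#' @export
run_report <- function(config = default_config(), fits = NULL, doses = NULL,
                       planning = NULL, recommendation = NULL, seed = NULL,
                       warnings = character()) {
  structure(list(schema_version = 1L,
                 created_with = paste0("psmaplan ",
                                       as.character(utils::packageVersion("psmaplan"))),
                 seed = seed, config = unclass(config),
                 fits = fits, doses = doses, planning = planning,
                 recommendation = recommendation, warnings = warnings),
            class = "run_report")
}

fit_summary_list <- function(f) {
  list(estimates = as.list(f$estimates), cv_pct = as.list(f$cv_pct),
       r2 = as.list(f$r2), fractional_sd = as.list(f$fractional_sd),
       objective = f$objective, aic = f$aic, n_obs = f$n_obs, k = f$k,
       converged = f$converged,
       at_bounds = names(which(f$at_bounds)),
       correlation = unname(apply(f$correlation, 1, as.list)))
}

#' Render a run report to files
#'
#' Writes a machine-readable JSON, a human-readable Markdown summary and CSV
#' tables (planning grid, fitted curves, dose report) with stable ordering so
#' re-rendering the same report is byte-identical. Sections that were not run
#' are marked explicitly.
#'
#' @param report a [run_report()].
#' @param dir output directory (created if needed).
#' @param formats subset of `c("json", "markdown", "csv")`.
#' @return named character vector of written paths, invisibly.
#' @export
render_report <- function(report, dir,
                          formats = c("json", "markdown", "csv")) {
  stopifnot(inherits(report, "run_report"))
  if (!dir.exists(dir))
    if (!dir.create(dir, recursive = TRUE, showWarnings = FALSE))
      stop("I/O error: cannot create output directory ", dir)
  paths <- character()
  if ("json" %in% formats) {
    js <- list(schema_version = report$schema_version,
               created_with = report$created_with,
               seed = report$seed, config = report$config,
               fits = if (is.null(report$fits)) "not run" else
                 lapply(report$fits, fit_summary_list),
               doses = if (is.null(report$doses)) "not run" else
                 lapply(report$doses, function(d) as.list(as.data.frame(d))),
               planning = if (is.null(report$planning)) "not run" else
                 as.list(as.data.frame(report$planning)),
               recommendation = if (is.null(report$recommendation)) "not run"
                 else unclass(report$recommendation[
                   setdiff(names(report$recommendation), "rows")]),
               warnings = report$warnings)
    p <- file.path(dir, "report.json")
    jsonlite::write_json(js, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths["json"] <- p
  }
  if ("markdown" %in% formats) {
    md <- c("# psmaplan run report", "",
            paste0("- schema version: ", report$schema_version),
            paste0("- seed: ", report$seed %||% "none"), "")
    md <- c(md, "## Fits", if (is.null(report$fits)) "not run" else
      unlist(lapply(names(report$fits), function(nm) {
        f <- report$fits[[nm]]
        c(paste0("### ", nm),
          paste0("- objective ", signif(f$objective, 6), ", AIC ",
                 signif(f$aic, 6), ", converged ", f$converged),
          paste0("- R^2: ", paste(sprintf("%s %.3f", names(f$r2), f$r2),
                                  collapse = ", ")))
      })), "")
    md <- c(md, "## Planning", if (is.null(report$planning)) "not run" else
      paste0(nrow(report$planning), " grid rows"), "")
    md <- c(md, "## Recommendation",
            if (is.null(report$recommendation)) "not run"
            else if (!report$recommendation$feasible) "infeasible"
            else sprintf("%g nmol at %.2f GBq (tumor BED %.1f Gy)",
                         report$recommendation$amount_nmol,
                         report$recommendation$activity_gbq,
                         report$recommendation$tumor_bed_gy), "")
    if (length(report$warnings))
      md <- c(md, "## Warnings", paste0("- ", report$warnings), "")
    p <- file.path(dir, "report.md")
    writeLines(md, p)
    paths["markdown"] <- p
  }
  if ("csv" %in% formats) {
    if (!is.null(report$planning)) {
      p <- file.path(dir, "planning_grid.csv")
      utils::write.csv(as.data.frame(report$planning), p, row.names = FALSE)
      paths["planning_csv"] <- p
    }
    if (!is.null(report$doses)) {
      p <- file.path(dir, "dose_report.csv")
      utils::write.csv(do.call(rbind, lapply(names(report$doses), function(nm) {
        d <- as.data.frame(report$doses[[nm]])
        cbind(id = nm, d)
      })), p, row.names = FALSE)
      paths["dose_csv"] <- p
    }
    if (!is.null(report$fits)) {
      p <- file.path(dir, "fitted_curves.csv")
      utils::write.csv(do.call(rbind, lapply(names(report$fits), function(nm)
        cbind(id = nm, report$fits[[nm]]$fitted))), p, row.names = FALSE)
      paths["fits_csv"] <- p
    }
  }
  invisible(paths)
}
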