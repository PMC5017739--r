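#' Sample a virtual patient
#'
#' Draws a reproducible virtual patient whose true parameters lie inside the
#' cohort envelopes of the configuration: receptor densities and release rates
#' for kidneys, salivary glands and two tumor lesions, salivary perfusion,
#' measured volumes, TER, BSA and the administered amount/activity. Densities
#' and tumor volumes that span decades are drawn log-uniformly, everything
#' else uniformly.
#'
#' @param seed integer seed (recorded in the patient).
#' @param config configuration list (`config$envelopes` holds the ranges).
#' @param noise named per-region fractional measurement SDs; defaults from
#'   `config$noise`.
#' @param background true muscle-background fraction used when generating
#'   measurements.
#' @return an object of class `"virtual_patient"`: a [patient_record()] plus
#'   `truth` (named true parameter vector), `noise`, `background`, `seed`.
#' @export
sample_virtual_patient <- function(seed, config = default_config(),
                                   noise = NULL, background = NULL) {
  ev <- lapply(config$envelopes, unlist)
  for (nm in names(ev)) {
    r <- ev[[nm]]
    if (length(r) == 2 && r[1] > r[2])
      stop("validation error: inverted envelope for ", nm)
  }
  runi <- function(r) stats::runif(1, r[1], r[2])
  rlog <- function(r) exp(stats::runif(1, log(r[1]), log(r[2])))
  withr::with_seed(seed, {
    truth <- c(
      r_kidneys = runi(ev$r_kidneys),
      r_salivary = runi(ev$r_salivary),
      r_tumor_1 = rlog(ev$r_tumor),
      r_tumor_2 = rlog(ev$r_tumor),
      lrel_kidneys = runi(ev$lrel_kidneys),
      lrel_salivary = runi(ev$lrel_salivary),
      lrel_tumor_1 = runi(ev$lrel_tumor),
      lrel_tumor_2 = runi(ev$lrel_tumor),
      f_sal = runi(ev$f_sal),
      background = background %||% config$background$fraction)
    rec <- patient_record(
      bsa = runi(ev$bsa_m2), ter = runi(ev$ter_ml_min),
      volumes = list(kidneys = runi(ev$kidney_volume_ml),
                     salivary_glands = runi(ev$parotid_volume_ml),
                     tumor_1 = rlog(ev$tumor_volume_ml),
                     tumor_2 = rlog(ev$tumor_volume_ml)),
      amount = runi(ev$amount_nmol), activity = runi(ev$activity_gbq))
  })
  rec$truth <- truth
  rec$noise <- unlist(noise %||% config$noise)
  rec$background <- truth[["background"]]
  rec$seed <- seed
  class(rec) <- c("virtual_patient", "patient_record")
  rec
}

#' Build the true model of a virtual patient
#'
#' @param patient a `virtual_patient`.
#' @param k_off dissociation rate (Model 1 default).
#' @param f_tu tumor perfusion, ml/g/min.
#' @param config configuration list.
#' @return list with `model` and `admin`.
#' @export
virtual_patient_model <- function(patient, k_off = NULL, f_tu = NULL,
                                  config = default_config()) {
  spec <- fit_spec(k_off = k_off, f_tu = f_tu, config = config)
  default_model_factory(patient, spec)(patient$truth)
}

#' Simulate noisy planar-style measurements
#'
#' Evaluates the true ROI curves (region activity fraction plus the known
#' muscle-background contamination) at the measurement schedule and applies
#' multiplicative log-normal noise with the per-region fractional SD (mean
#' preserved, values truncated at 0). `noise = 0` returns the exact curves.
#'
#' @param patient a `virtual_patient` (or list with `truth` etc.).
#' @param schedule measurement times in min (default 0.5 h, 2 h, 1 d, 2 d,
#'   3 d).
#' @param regions measured regions.
#' @param seed seed for the noise draws (default: derived from the patient
#'   seed).
#' @param k_off,f_tu,config forwarded to [virtual_patient_model()].
#' @return list of [time_activity_dataset()]s.
#' @export
simulate_measurements <- function(patient, schedule = NULL,
                                  regions = c("tumor_1", "tumor_2", "kidneys",
                                              "salivary_glands", "total_body"),
                                  seed = NULL, k_off = NULL, f_tu = NULL,
                                  config = default_config()) {
  schedule <- schedule %||% unlist(config$schedule_min)
  if (any(schedule < 0) || any(schedule > config$solver$t_end_min))
    stop("validation error: schedule outside simulated horizon")
  fm <- virtual_patient_model(patient, k_off = k_off, f_tu = f_tu,
                              config = config)
  # generation uses the dosimetry-grade solver tolerances, not the looser
  # fit-grade ones, so noise-free datasets sit on the true model curve
  sim <- simulate_pbpk(fm$model, fm$admin,
                       solver_settings(t_end = max(schedule), config = config),
                       output_times = sort(unique(schedule)))
  seed <- seed %||% (patient$seed + 10000L)
  noise <- patient$noise
  withr::with_seed(seed, {
    out <- lapply(regions, function(rg) {
      bg <- if (rg == "total_body") 0 else patient$background
      p <- predict_roi(sim, rg, bg)$value
      cv <- if (rg %in% names(noise)) noise[[rg]] else noise[[1]]
      v <- if (cv > 0) {
        sdlog <- sqrt(log(1 + cv^2))
        p * exp(stats::rnorm(length(p), -sdlog^2 / 2, sdlog)) # mean-preserving
      } else p
      time_activity_dataset(rg, sort(unique(schedule)),
                            pmin(pmax(v, 0), 1.2),
                            sd = cv * p)
    })
  })
  out
}

#' Write / read time-activity datasets
#'
#' CSV round-trip of measurement data (columns `patient_id`, `region`,
#' `time_min`, `fraction_ia`, optional `sd`). The true generating parameters
#' are written to a separate "truth" sidecar JSON so that fitting code cannot
#' read them by accident.
#'
#' @param datasets list of [time_activity_dataset()]s.
#' @param path CSV output path.
#' @param patient_id identifier written to the file.
#' @param truth optional named vector written to `<path>.truth.json`.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(datasets, path, patient_id = "P1", truth = NULL) {
  if (inherits(datasets, "time_activity_dataset")) datasets <- list(datasets)
  df <- do.call(rbind, lapply(datasets, function(d) {
    out <- data.frame(patient_id = patient_id, region = d$region,
                      time_min = d$time_min, fraction_ia = d$value)
    if ("sd" %in% names(d)) out$sd <- d$sd
    out
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(truth))
    jsonlite::write_json(as.list(truth), paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_dataset
#' @param patient filter on `patient_id` when reading (default: all).
#' @return `read_dataset`: named list of datasets per patient, each a list of
#'   [time_activity_dataset()]s.
#' @export
read_dataset <- function(path, patient = NULL) {
  raw <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                  error = function(e)
                    stop("parse error reading '", path, "': ",
                         conditionMessage(e)))
  need <- c("patient_id", "region", "time_min", "fraction_ia")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("parse error: missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(raw) == 0) {
    warning("empty dataset file: ", path)
    return(list())
  }
  bad <- which(!is.finite(raw$time_min) | !is.finite(raw$fraction_ia))
  if (length(bad))
    stop("parse error: malformed numeric value at data line ", bad[1] + 1)
  if (!is.null(patient)) raw <- raw[raw$patient_id %in% patient, ]
  lapply(split(raw, raw$patient_id), function(pp) {
    lapply(split(pp, pp$region), function(d) {
      d <- d[order(d$time_min), ]
      time_activity_dataset(d$region[1], d$time_min, d$fraction_ia,
                            sd = if ("sd" %in% names(d)) d$sd)
    })
  })
}
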