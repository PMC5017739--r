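#' Receptor map
#'
#' PSMA binding-site densities (nmol per litre of tissue) for the
#' receptor-positive regions. The densities of kidneys, salivary glands and
#' the tumor lesions are patient-specific (fitted); liver, spleen, GI tract
#' and prostate use fixed multiples of the reference kidney density.
#'
#' @param kidneys,salivary_glands,tumor_1,tumor_2 densities in nmol/l.
#' @param relative named list of multipliers for the non-fitted tissues
#'   (defaults from the configuration).
#' @param config configuration list.
#' @return an object of class `"receptor_map"`, a named numeric vector of
#'   densities for all PSMA-positive regions.
#' @export
receptor_map <- function(kidneys = NULL, salivary_glands = NULL,
                         tumor_1 = NULL, tumor_2 = NULL,
                         relative = NULL, config = default_config()) {
  rc <- config$receptors
  dens <- c(kidneys = kidneys %||% rc$kidneys,
            salivary_glands = salivary_glands %||% rc$salivary_glands,
            tumor_1 = tumor_1 %||% rc$tumor_1,
            tumor_2 = tumor_2 %||% rc$tumor_2)
  rel <- relative %||% rc$relative
  ref <- rc$reference_kidney_density
  dens <- c(dens, vapply(rel, function(f) f * ref, 0))
  if (any(dens < 0)) stop("validation error: receptor densities must be >= 0")
  structure(dens, class = "receptor_map")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ligand kinetic parameters
#'
#' Association/dissociation rates, internalization and cellular release rates,
#' physical decay and the unspecific kidney-uptake settings. `k_off` selects
#' the candidate binding model: 0.046 min^-1 (Model 1) or 0.46 min^-1
#' (Model 2).
#'
#' @param k_on association rate, l nmol^-1 min^-1.
#' @param k_off dissociation rate, min^-1.
#' @param lambda_int internalization rate, min^-1 (all tissues).
#' @param lambda_release named list/vector of release rates (min^-1) for
#'   `kidneys`, `salivary_glands`, `tumor_1`, `tumor_2` and `other`.
#' @param config configuration list.
#' @return an object of class `"ligand_params"`.
#' @export
ligand_params <- function(k_on = NULL, k_off = NULL, lambda_int = NULL,
                          lambda_release = list(), config = default_config()) {
  lg <- config$ligand
  lr <- utils::modifyList(lg$lambda_release, as.list(lambda_release))
  out <- structure(list(
    k_on = k_on %||% lg$k_on,
    k_off = k_off %||% lg$k_off,
    lambda_int = lambda_int %||% lg$lambda_int,
    lambda_release = lr,
    lambda_phys = log(2) / lg$half_life_min,
    molar_mass_factor = lg$molar_mass_factor,
    molar_activity = lg$molar_activity_gbq_nmol,
    unspecific_kidney_fraction = lg$unspecific_kidney_fraction,
    renal_clearance_ter_factor = lg$renal_clearance_ter_factor,
    catabolite_clearance_ter_factor = lg$catabolite_clearance_ter_factor
  ), class = "ligand_params")
  with(out, {
    if (k_on <= 0 || lambda_phys <= 0) stop("validation error: k_on and lambda_phys must be > 0")
    if (k_off < 0 || lambda_int < 0 || any(unlist(lr) < 0))
      stop("validation error: negative rate")
  })
  out
}

#' Build the whole-body PBPK model for one patient
#'
#' Assembles the closed compartmental system: every organ has a vascular and
#' an interstitial-free sub-compartment connected to the central serum pool by
#' serum flow and to each other by PS-limited transcapillary exchange;
#' PSMA-positive organs additionally have receptor-bound and internalized
#' sub-compartments. Labeled and unlabeled ligand share all rate parameters
#' and compete for the same free-receptor pool. Released label enters a
#' non-binding serum catabolite pool cleared renally; free serum peptide is
#' filtered at the patient's tubular extraction rate, with a small configured
#' fraction retained as unspecific kidney uptake.
#'
#' @param physiology a [physiology_set()].
#' @param receptors a [receptor_map()].
#' @param ligand a [ligand_params()].
#' @param config configuration list.
#' @return an object of class `"pbpk_model"`.
#' @export
build_model <- function(physiology, receptors, ligand,
                        config = default_config()) {
  stopifnot(inherits(physiology, "physiology_set"))
  validate_physiology(physiology)
  org <- physiology$organs
  dens <- rep(0, nrow(org))
  names(dens) <- org$name
  for (nm in names(receptors)) {
    if (!nm %in% org$name)
      stop("configuration error: receptor entry for unknown organ '", nm, "'")
    dens[nm] <- receptors[[nm]]
  }
  if (any(dens[org$psma & org$name %in% names(receptors)] < 0))
    stop("validation error: negative receptor density")
  # total receptor amount per organ: density [nmol/l] * volume [ml] / 1000
  rtot <- dens * org$volume_ml / 1000
  lrel <- vapply(org$name, function(nm) {
    if (!org$psma[org$name == nm]) return(0)
    lr <- ligand$lambda_release
    if (!is.null(lr[[nm]])) lr[[nm]] else lr$other
  }, 0)
  lint <- ifelse(org$psma, ligand$lambda_int, 0)

  structure(list(
    organs = org,
    rtot = unname(rtot), lint = unname(lint), lrel = unname(lrel),
    serum_volume = physiology$serum_volume,
    ter = physiology$ter,
    cl_renal = ligand$renal_clearance_ter_factor * physiology$ter,
    k_on = ligand$k_on, k_off = ligand$k_off,
    lambda_phys = ligand$lambda_phys,
    fu = ligand$unspecific_kidney_fraction,
    cl_cat = ligand$catabolite_clearance_ter_factor * physiology$ter,
    physiology = physiology, receptors = receptors, ligand = ligand,
    layout = model_layout(org)
  ), class = "pbpk_model")
}

# state indices (1-based, single species block)
model_layout <- function(org) {
  off <- integer(nrow(org))
  k <- 4L # 1 serum, 2 catabolite, 3 urine
  for (o in seq_len(nrow(org))) {
    off[o] <- k
    k <- k + if (org$psma[o]) 4L else 2L
  }
  region <- lapply(seq_len(nrow(org)), function(o) {
    n <- if (org$psma[o]) 4L else 2L
    seq.int(off[o], length.out = n)
  })
  names(region) <- org$name
  list(offset = off, m = k - 1L, serum = 1L, catabolite = 2L, urine = 3L,
       region = region)
}

#' @export
print.pbpk_model <- function(x, ...) {
  cat(sprintf("<pbpk_model> %d organs (%d PSMA+), %d states per species\n",
              nrow(x$organs), sum(x$organs$psma), x$layout$m))
  cat(sprintf("  k_on %.3g l/nmol/min, k_off %.3g 1/min (Model %s), TER %.0f ml/min\n",
              x$k_on, x$k_off, if (abs(x$k_off - 0.046) < 1e-9) "1" else
                if (abs(x$k_off - 0.46) < 1e-9) "2" else "custom", x$ter))
  invisible(x)
}

#' Median-parameter patient
#'
#' Convenience constructor for the cohort-median patient: median measured
#' volumes and TER with the median fitted parameters (receptor densities,
#' release rates, salivary perfusion) from the configuration defaults.
#'
#' @param config configuration list.
#' @param k_off optional dissociation rate override.
#' @param f_tu tumor perfusion (ml/g/min).
#' @return a `pbpk_model`.
#' @export
median_patient_model <- function(config = default_config(), k_off = NULL,
                                 f_tu = NULL) {
  phys <- physiology_set(
    bsa = 2.0, ter = 198,
    volumes = list(kidneys = 311, salivary_glands = 29,
                   tumor_1 = 1.5, tumor_2 = 3),
    f_sal = 0.16, f_tu = f_tu, config = config)
  build_model(phys, receptor_map(config = config),
              ligand_params(k_off = k_off, config = config), config = config)
}
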