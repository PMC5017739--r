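#' Patient physiology
#'
#' Builds the per-organ physiological table for one patient from the reference
#' adult in the configuration: organ masses and serum flows scale linearly
#' with body weight, measured volumes (kidneys, parotid/salivary glands,
#' tumor lesions) override the scaled reference, and vascular/interstitial
#' fractions and permeability-surface-area (PS) densities are taken from the
#' configuration. Body weight may be given directly or derived from body
#' surface area by inverting the Du Bois formula at the configured height.
#'
#' @param bsa body surface area in m^2 (used when `weight` is `NULL`).
#' @param weight body weight in kg, overrides `bsa`.
#' @param ter tubular extraction rate in ml/min.
#' @param volumes named list of measured tissue volumes in ml; recognized
#'   names: `kidneys`, `salivary_glands`, `tumor_1`, `tumor_2`.
#' @param f_sal salivary serum flow per mass (ml/g/min), a fitted parameter.
#' @param f_tu tumor perfusion (ml/g/min), fixed (default 0.5).
#' @param config configuration list.
#' @return an object of class `"physiology_set"`: a list with the organ table
#'   (`organs`), central serum volume, total serum flow, TER, weight and BSA.
#' @export
physiology_set <- function(bsa = NULL, weight = NULL, ter,
                           volumes = list(),
                           f_sal = NULL, f_tu = NULL,
                           config = default_config()) {
  ref <- config$reference
  if (is.null(weight)) {
    if (is.null(bsa)) stop("either weight or bsa must be given")
    weight <- weight_from_bsa(bsa, ref$height_m)
  }
  if (is.null(bsa)) bsa <- 0.007184 * weight^0.425 * (ref$height_m * 100)^0.725
  if (ter <= 0) stop("ter must be positive")
  scale <- weight / ref$body_weight_kg

  tab <- config$physiology
  required <- c("kidneys", "salivary_glands", "tumor_1", "tumor_2", "liver",
                "spleen", "gi_tract", "prostate", "muscle", "fat", "lungs",
                "bone", "red_marrow", "heart", "brain", "skin", "rest")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("configuration error: missing organ entries: ",
         paste(missing, collapse = ", "))

  org <- do.call(rbind, lapply(required, function(nm) {
    e <- tab[[nm]]
    mass <- e$mass_g * scale
    if (nm %in% names(volumes)) mass <- volumes[[nm]] # density 1 g/ml
    perf <- e$perfusion
    if (nm == "salivary_glands" && !is.null(f_sal)) perf <- f_sal
    if (nm %in% c("tumor_1", "tumor_2") && !is.null(f_tu)) perf <- f_tu
    data.frame(name = nm, mass_g = mass, volume_ml = mass,
               perfusion = perf, flow = perf * mass,
               vascular_fraction = e$vascular_fraction,
               interstitial_fraction = e$interstitial_fraction,
               ps = e$ps_per_g * mass, psma = isTRUE(e$psma),
               stringsAsFactors = FALSE)
  }))
  org$vascular_ml <- org$volume_ml * org$vascular_fraction
  org$interstitial_ml <- org$volume_ml * org$interstitial_fraction

  serum_total <- ref$plasma_volume_ml * scale
  serum_central <- serum_total - sum(org$vascular_ml)
  phys <- structure(list(
    organs = org,
    serum_volume = serum_central,
    serum_volume_total = serum_total,
    total_flow = sum(org$flow),
    ter = ter, body_weight = weight, body_surface_area = bsa
  ), class = "physiology_set")
  validate_physiology(phys)
  phys
}

weight_from_bsa <- function(bsa, height_m) {
  # invert Du Bois: bsa = 0.007184 * w^0.425 * h_cm^0.725
  (bsa / (0.007184 * (height_m * 100)^0.725))^(1 / 0.425)
}

#' Validate a physiology set
#'
#' Checks the structural invariants: positive volumes and flows, vascular plus
#' interstitial fractions below one, and consistency of the total serum flow
#' with the sum of organ serum flows.
#'
#' @param phys a `physiology_set`.
#' @return `phys`, invisibly; errors on violation.
#' @export
validate_physiology <- function(phys) {
  org <- phys$organs
  if (any(org$volume_ml <= 0) || any(org$flow <= 0) || any(org$ps <= 0))
    stop("validation error: all organ volumes, flows and PS products must be > 0")
  if (any(org$vascular_fraction + org$interstitial_fraction >= 1))
    stop("validation error: vascular + interstitial fraction must be < 1")
  if (phys$serum_volume <= 0)
    stop("validation error: central serum volume non-positive")
  if (abs(phys$total_flow - sum(org$flow)) > 1e-9 * phys$total_flow)
    stop("validation error: organ serum flows do not sum to the total serum flow")
  invisible(phys)
}

#' @export
print.physiology_set <- function(x, ...) {
  cat(sprintf("<physiology_set> weight %.1f kg, BSA %.2f m^2, TER %.0f ml/min\n",
              x$body_weight, x$body_surface_area, x$ter))
  cat(sprintf("  central serum %.0f ml, total serum flow %.0f ml/min, %d organs\n",
              x$serum_volume, x$total_flow, nrow(x$organs)))
  invisible(x)
}
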