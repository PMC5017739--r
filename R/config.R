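#' Load the package configuration
#'
#' Reads the default YAML configuration shipped with the package and, when
#' `path` is given, recursively merges the user file over the defaults. The
#' configuration holds the fixed physiological constants (reference organ
#' masses, perfusions, vascular/interstitial fractions, permeability-surface
#' products), ligand kinetics, radiobiological parameters, S-value references,
#' dose-constraint levels and solver settings. Every value is echoed into run
#' reports for provenance.
#'
#' @param path optional path to a user YAML file overriding defaults.
#' @return a nested list with class `"psmaplan_config"`.
#' @export
load_config <- function(path = NULL) {
  cfg <- yaml::read_yaml(system.file("extdata", "default_config.yaml",
                                     package = "psmaplan", mustWork = TRUE))
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, user)
  }
  class(cfg) <- c("psmaplan_config", "list")
  cfg
}

#' @rdname load_config
#' @export
default_config <- function() {
  env <- .psmaplan_env
  if (is.null(env$config)) env$config <- load_config()
  env$config
}

.psmaplan_env <- new.env(parent = emptyenv())

#' Lu-177 physical decay constant
#'
#' @param config configuration list.
#' @return decay constant in 1/min (default `log(2)/9573`).
#' @export
lambda_phys <- function(config = default_config()) {
  log(2) / config$ligand$half_life_min
}

#' Convert peptide amount between nmol and micrograms
#'
#' Uses the ligand molar-mass factor (1.66 ug per nmol by default).
#'
#' @param amount amount in nmol (or ug for the inverse).
#' @param config configuration list.
#' @return mass in ug (`nmol_to_mass`) or amount in nmol (`mass_to_nmol`).
#' @examples
#' nmol_to_mass(142) # ~236 ug
#' @export
nmol_to_mass <- function(amount, config = default_config()) {
  if (any(amount < 0)) stop("amount must be non-negative")
  amount * config$ligand$molar_mass_factor
}

#' @rdname nmol_to_mass
#' @param mass mass in ug.
#' @export
mass_to_nmol <- function(mass, config = default_config()) {
  if (any(mass < 0)) stop("mass must be non-negative")
  mass / config$ligand$molar_mass_factor
}
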