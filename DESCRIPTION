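Package: psmaplan
Title: Whole-Body PBPK Modelling, Dosimetry and Treatment Planning for
    Lu-177 PSMA Radioligand Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the coupled kinetics of labeled and unlabeled
    PSMA-targeting peptide in a whole-body physiologically based
    pharmacokinetic (PBPK) model, fits patient-specific parameters
    (binding-site densities, cellular release rates, salivary perfusion,
    measurement background) to planar time-activity data with
    relative-variance weighting and Akaike model selection, converts the
    kinetics into absorbed doses and biologically effective doses (BED)
    via MIRD S-values and the Lea-Catcheside protraction factor, and
    inverts kidney, salivary-gland and red-marrow dose constraints to find
    the peptide amount and injected activity that maximize tumor BED.
    Includes a synthetic-data generator for virtual patients so the whole
    pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
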