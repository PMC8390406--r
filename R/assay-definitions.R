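#' Chromogenic assay definitions
#'
#' One row per enzyme assay: substrate identity, assay conditions and the
#' stoichiometric constants needed to convert dye release into substrate
#' hydrolysis. The four assays target lipase (pNP-palmitate), alpha- and
#' beta-glucosidase (pNP-glucopyranosides) and protease (azocasein). The
#' p-nitrophenyl substrates release one mole of pNP per mole hydrolyzed;
#' azocasein dye release is expressed in tyrosine equivalents and routed
#' through the azocasein stoichiometry of the conversion table.
#'
#' `substrate_molar_mass` is the molar mass of the assay substrate in g/mol
#' (pNP-palmitate 378, pNP-glucopyranosides 301, azocasein ~23,000).
#' `biomolecule` maps each enzyme class to the influent biomolecule pool it
#' hydrolyzes, which selects the COD conversion factor.
#'
#' @return A tibble with one row per enzyme class.
#' @export
#' @examples
#' assay_definitions()
assay_definitions <- function() {
  tibble::tibble(
    enzyme_class = c("lipase", "alpha_glucosidase", "beta_glucosidase", "protease"),
    substrate_name = c(
      "pNP-palmitate", "pNP-alpha-glucopyranoside",
      "pNP-beta-glucopyranoside", "azocasein"
    ),
    substrate_concentration = c(20, 1, 1, 0.2),
    concentration_unit = c("mM", "mM", "mM", "% w/v"),
    assay_length_h = c(1.25, 1.25, 1.25, 2.5),
    wavelength_nm = c(410, 400, 400, 440),
    dye = c("pNP", "pNP", "pNP", "azo_dye"),
    dye_per_substrate = c(1, 1, 1, NA_real_),
    substrate_molar_mass = c(378, 301, 301, 23000),
    biomolecule = c("lipid", "carbohydrate", "carbohydrate", "protein")
  )
}

enzyme_classes <- function() assay_definitions()$enzyme_class

sludge_fractions <- function() {
  c("mixed", "large_granules", "crushed_granules", "small_granules",
    "flocs", "bulk", "influent")
}

liquid_fractions <- function() c("bulk", "influent")

#' Default dye calibration curves
#'
#' Calibration slopes relate absorbance to dye concentration in the measured
#' solution (AU per umol dye per mL). Standards are assumed to have been
#' carried through the same TCA/NaOH workup as the samples, so no additional
#' dilution factor applies by default. Replace with measured curves via
#' [read_calibration()] for real data.
#'
#' @return A tibble with columns `dye`, `slope`, `intercept`, `range_lo`,
#'   `range_hi`.
#' @export
default_calibration <- function() {
  tibble::tibble(
    dye = c("pNP", "azo_dye"),
    slope = c(4.0, 0.5),
    intercept = c(0.05, 0.05),
    range_lo = c(0, 0),
    range_hi = c(2.5, 2.5)
  )
}

#' Read a calibration-curve table from CSV
#'
#' Expects columns `dye`, `slope`, `intercept`, `range_lo`, `range_hi`.
#'
#' @param path Path to the calibration CSV.
#' @return A calibration tibble.
#' @export
read_calibration <- function(path) {
  cal <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("dye", "slope", "intercept", "range_lo", "range_hi")
  missing <- setdiff(required, names(cal))
  if (length(missing) > 0) {
    abort(paste0("calibration file misses column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (any(cal$slope <= 0)) abort("calibration slope must be > 0")
  cal
}
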