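#' Stoichiometric and COD conversion table
#'
#' Collects the constants that turn dye-release rates into substrate-mass and
#' COD-hydrolysis rates. The azocasein stoichiometry (6.9 tyrosine
#' equivalents per mole of azocasein, i.e. 1/6.9 ~ 0.14 mol protein per mol
#' Tyr eq) is a property of the substrate. The COD factors per gram of
#' substrate are literature defaults (protein 1.5, carbohydrate 1.07, lipid
#' 2.0 g COD/g) shipped for convenience, not measured values: override them
#' with site-specific numbers where available.
#'
#' @param tyr_per_mol_azocasein Tyrosine equivalents per mole azocasein
#'   (default 6.9).
#' @param cod_factors Named numeric: g COD per g substrate for `protein`,
#'   `carbohydrate`, `lipid`.
#' @param azocasein_molar_mass g/mol (default 23000).
#' @param lipase_mass_basis Whether lipase substrate mass uses the full
#'   pNP-palmitate conjugate (378 g/mol, default) or palmitate alone
#'   (256 g/mol).
#' @return A list of class `conversion_table`.
#' @export
conversion_table <- function(tyr_per_mol_azocasein = 6.9,
                             cod_factors = c(protein = 1.5,
                                             carbohydrate = 1.07,
                                             lipid = 2.0),
                             azocasein_molar_mass = 23000,
                             lipase_mass_basis = c("pNP_palmitate", "palmitate")) {
  lipase_mass_basis <- match.arg(lipase_mass_basis)
  if (tyr_per_mol_azocasein <= 0) abort("tyr_per_mol_azocasein must be > 0")
  if (any(cod_factors <= 0)) abort("COD factors must be > 0")
  if (azocasein_molar_mass <= 0) abort("azocasein molar mass must be > 0")
  structure(
    list(
      tyr_per_mol_azocasein = tyr_per_mol_azocasein,
      protein_per_tyr_eq = 1 / tyr_per_mol_azocasein,
      cod_factors = cod_factors,
      azocasein_molar_mass = azocasein_molar_mass,
      lipase_mass_basis = lipase_mass_basis,
      lipase_molar_mass = if (lipase_mass_basis == "pNP_palmitate") 378 else 256
    ),
    class = "conversion_table"
  )
}

#' Tyrosine-equivalent rate to protein hydrolysis rate
#'
#' Azocasein contains `tyr_per_mol_azocasein` tyrosine equivalents per mole,
#' so one mole of Tyr equivalents corresponds to 1/6.9 ~ 0.14 moles of
#' protein hydrolyzed.
#'
#' @param tyr_eq_rate Rate in umol Tyr eq/h (vectorized).
#' @param table A [conversion_table()].
#' @return Protein hydrolysis rate in umol/h.
#' @export
tyr_eq_to_protein_mol <- function(tyr_eq_rate, table = conversion_table()) {
  if (any(tyr_eq_rate < 0)) abort("rate must be >= 0")
  tyr_eq_rate * table$protein_per_tyr_eq
}

#' Dye-release rate to substrate-mass hydrolysis rate
#'
#' pNP conjugates release one mole of dye per mole of substrate hydrolyzed;
#' protease rates in Tyr equivalents are first converted to moles of protein
#' via [tyr_eq_to_protein_mol()]. The molar rate times the substrate molar
#' mass gives mg substrate hydrolyzed per hour.
#'
#' @param rate Dye-release rate in umol dye/h (vectorized).
#' @param enzyme_class Character vector of enzyme classes, recycled against
#'   `rate`.
#' @param table A [conversion_table()].
#' @param assay Assay definition table; see [assay_definitions()].
#' @return Substrate hydrolysis rate in mg/h.
#' @export
#' @examples
#' dye_rate_to_substrate_mass_rate(1, "alpha_glucosidase") # 0.301 mg/h
dye_rate_to_substrate_mass_rate <- function(rate, enzyme_class,
                                            table = conversion_table(),
                                            assay = assay_definitions()) {
  if (any(rate < 0)) abort("rate must be >= 0")
  bad <- setdiff(unique(enzyme_class), assay$enzyme_class)
  if (length(bad) > 0) {
    abort(paste0("unknown enzyme class: ", paste(bad, collapse = ", ")))
  }
  d <- tibble::tibble(rate = rate, enzyme_class = enzyme_class) |>
    dplyr::left_join(
      dplyr::select(assay, "enzyme_class", "dye_per_substrate",
                    "substrate_molar_mass"),
      by = "enzyme_class"
    ) |>
    dplyr::mutate(
      mol_rate = dplyr::case_when(
        .data$enzyme_class == "protease" ~
          .data$rate * table$protein_per_tyr_eq,
        TRUE ~ .data$rate / .data$dye_per_substrate
      ),
      molar_mass = dplyr::case_when(
        .data$enzyme_class == "protease" ~ table$azocasein_molar_mass,
        .data$enzyme_class == "lipase" ~ table$lipase_molar_mass,
        TRUE ~ .data$substrate_molar_mass
      )
    )
  # umol/h * g/mol = ug/h; divide by 1000 for mg/h
  d$mol_rate * d$molar_mass / 1000
}

#' Substrate-mass rate to COD rate
#'
#' @param mass_rate Rate in mg substrate/h (vectorized).
#' @param biomolecule_class `protein`, `carbohydrate` or `lipid`, recycled
#'   against `mass_rate`.
#' @param table A [conversion_table()].
#' @return COD hydrolysis rate in mg COD/h.
#' @export
mass_to_cod <- function(mass_rate, biomolecule_class,
                        table = conversion_table()) {
  bad <- setdiff(unique(biomolecule_class), names(table$cod_factors))
  if (length(bad) > 0) {
    abort(paste0("no COD factor for class: ", paste(bad, collapse = ", ")))
  }
  mass_rate * unname(table$cod_factors[biomolecule_class])
}

#' Dye-release rate straight to COD rate
#'
#' Convenience chain: [dye_rate_to_substrate_mass_rate()] then
#' [mass_to_cod()], using the enzyme-to-biomolecule mapping of the assay
#' table.
#'
#' @inheritParams dye_rate_to_substrate_mass_rate
#' @return COD hydrolysis rate in mg COD/h.
#' @export
dye_rate_to_cod_rate <- function(rate, enzyme_class,
                                 table = conversion_table(),
                                 assay = assay_definitions()) {
  mass <- dye_rate_to_substrate_mass_rate(rate, enzyme_class, table, assay)
  biomol <- assay$biomolecule[match(enzyme_class, assay$enzyme_class)]
  mass_to_cod(mass, biomol, table)
}
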