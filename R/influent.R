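influent_analytes <- function() {
  c("tcod", "scod", "bod5", "tss", "vss",
    "protein_sol", "protein_tot", "carb_sol", "carb_tot",
    "humic_sol", "humic_tot", "lipid", "vfa")
}

influent_pairs <- function() {
  tibble::tibble(
    soluble = c("scod", "protein_sol", "carb_sol", "humic_sol"),
    total = c("tcod", "protein_tot", "carb_tot", "humic_tot")
  )
}

#' Read an influent composition table from CSV
#'
#' One row per sampling day with columns `date`, `weather` (`DWF`/`WWF`) and
#' the analyte concentrations in g/m^3 (COD basis where applicable):
#' `tcod, scod, bod5, tss, vss, protein_sol, protein_tot, carb_sol,
#' carb_tot, humic_sol, humic_tot, lipid, vfa`. Missing measurements are
#' empty cells. Soluble concentrations must not exceed their paired totals.
#'
#' @param path Path to the influent CSV.
#' @return A validated tibble.
#' @export
read_influent <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         date = readr::col_character(),
                         weather = readr::col_character(),
                         .default = readr::col_double()
                       ))
  validate_influent(x)
}

validate_influent <- function(x) {
  missing <- setdiff(c("date", "weather", influent_analytes()), names(x))
  if (length(missing) > 0) {
    abort(paste0("influent table misses column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (!all(x$weather %in% c("DWF", "WWF"))) {
    abort("weather must be DWF or WWF")
  }
  vals <- as.matrix(x[influent_analytes()])
  if (any(vals < 0, na.rm = TRUE)) abort("negative concentrations")
  pr <- influent_pairs()
  for (i in seq_len(nrow(pr))) {
    s <- x[[pr$soluble[i]]]; t <- x[[pr$total[i]]]
    both <- !is.na(s) & !is.na(t)
    if (any(s[both] > t[both])) {
      abort(paste0("soluble ", pr$soluble[i], " exceeds total ", pr$total[i]))
    }
  }
  tibble::as_tibble(x)
}

#' Influent composition measured during the sampling campaign
#'
#' The shipped fixture: three dry-weather sampling days plus one wet-weather
#' day, concentrations in g/m^3 (g COD/m^3 for the biomolecule pools). The
#' VFA entries are ambiguous in the source table and are stored as 58/9/40;
#' no summary in this package depends on them.
#'
#' @return A tibble, one row per sampling day.
#' @export
influent_campaign <- function() {
  read_influent(system.file("extdata", "influent_garmerwolde.csv",
                            package = "agshydro", mustWork = TRUE))
}

#' Average influent composition over a sampling campaign
#'
#' Per-analyte arithmetic mean with pairwise deletion of missing values (the
#' campaign table has holes; nothing is imputed). Days with the excluded
#' weather condition are dropped for the analytes named in
#' `weather_analytes` — by default only the COD concentrations, since storm
#' dilution invalidates a COD average but sparse analytes (measured on
#' whichever days a sample existed) keep all their values. Set
#' `weather_analytes = NULL` to apply the weather filter to every analyte.
#'
#' @param samples Influent tibble; see [read_influent()].
#' @param exclude_weather Weather classes to exclude (default `"WWF"`).
#' @param weather_analytes Analytes the weather filter applies to
#'   (default `c("tcod", "scod")`); `NULL` means all.
#' @return A one-row tibble of unrounded means (report rounding is applied
#'   at presentation time).
#' @export
#' @examples
#' campaign_average(influent_campaign())
campaign_average <- function(samples, exclude_weather = "WWF",
                             weather_analytes = c("tcod", "scod")) {
  samples <- validate_influent(samples)
  analytes <- influent_analytes()
  weather_analytes <- weather_analytes %||% analytes
  keep_all <- !(samples$weather %in% exclude_weather)
  out <- purrr::map_dbl(setNames(analytes, analytes), function(a) {
    keep <- if (a %in% weather_analytes) keep_all else rep(TRUE, nrow(samples))
    v <- samples[[a]][keep]
    v <- v[!is.na(v)]
    if (length(v) == 0 && !any(keep)) abort("all samples excluded")
    if (length(v) == 0) return(NA_real_)
    mean(v)
  })
  tibble::as_tibble_row(out)
}

#' Convert a measured mass concentration to COD
#'
#' @param concentration Concentration in g/m^3 as measured (vectorized).
#' @param analyte_class `protein`, `carbohydrate` or `lipid`.
#' @param table A [conversion_table()].
#' @return Concentration in g COD/m^3.
#' @export
mass_to_cod_concentration <- function(concentration, analyte_class,
                                      table = conversion_table()) {
  if (any(concentration < 0)) abort("concentration must be >= 0")
  mass_to_cod(concentration, analyte_class, table)
}

#' Correct an activity measured on settled influent back to the original basis
#'
#' Influent with low activity is concentrated by settling (e.g. 2 L settled
#' to a final 250 mL) before the assay; the measured per-mL activity is
#' rescaled by the volume ratio to the original-influent basis. When the
#' settled fraction is known to carry only part of the total activity
#' (`settled_activity_share` < 1, e.g. 0.43 measured for lipase), an
#' extrapolated total is also reported and flagged, since dividing by the
#' share assumes the supernatant activity scales the same way.
#'
#' @param measured_specific_activity Activity of the settled concentrate,
#'   umol (mL h)^-1.
#' @param initial_volume_l Influent volume before settling (L).
#' @param final_volume_l Concentrate volume after settling (L), <= initial.
#' @param settled_activity_share Fraction of the total influent activity
#'   retained in the settled concentrate, in (0, 1] (default 1).
#' @return One-row tibble: `activity_original_basis`,
#'   `activity_extrapolated_total`, `extrapolated` flag.
#' @export
settling_correction <- function(measured_specific_activity,
                                initial_volume_l, final_volume_l,
                                settled_activity_share = 1) {
  if (final_volume_l <= 0) abort("final volume must be > 0")
  if (final_volume_l > initial_volume_l) {
    abort("final volume exceeds initial volume")
  }
  if (settled_activity_share <= 0 || settled_activity_share > 1) {
    abort("settled activity share must be in (0, 1]")
  }
  base <- measured_specific_activity * final_volume_l / initial_volume_l
  tibble::tibble(
    activity_original_basis = base,
    activity_extrapolated_total = base / settled_activity_share,
    extrapolated = settled_activity_share < 1
  )
}
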