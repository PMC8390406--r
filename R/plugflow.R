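#' Feeding scenario for the plug-flow capacity model
#'
#' @param feed_volume_m3 Influent volume fed per cycle (default 3870 m^3).
#' @param duration_h Feeding duration (default 1 h).
#' @param include_influent_activity Add the enzymes carried by the influent
#'   itself to the capacity (default `FALSE`: the capacity is presented as
#'   sludge hydrolysis, and influent flocs are unlikely to act during the
#'   feeding).
#' @param include_bulk_activity Add dissolved bulk-liquid enzymes
#'   (default `FALSE`).
#' @return A list of class `feeding_scenario`.
#' @export
feeding_scenario <- function(feed_volume_m3 = 3870, duration_h = 1,
                             include_influent_activity = FALSE,
                             include_bulk_activity = FALSE) {
  if (feed_volume_m3 <= 0) abort("feed volume must be > 0")
  if (duration_h <= 0) abort("duration must be > 0")
  structure(
    list(
      feed_volume_m3 = feed_volume_m3,
      duration_h = duration_h,
      include_influent_activity = include_influent_activity,
      include_bulk_activity = include_bulk_activity
    ),
    class = "feeding_scenario"
  )
}

#' Discretize the stratified sludge bed into a cascade of CSTR segments
#'
#' The settled bed is stratified by settling velocity: large granules at the
#' bottom, then small granules, then flocs. The bed is split into `n` equal
#' segments (equal VS by default) filled bottom-up in that order by a
#' cumulative-fill rule, and influent entering from the bottom activates
#' segment j at time `(j - 1) * duration / n` (the bottom segment is active
#' from t = 0).
#'
#' Segments are equal-VS because the per-segment activity bookkeeping is
#' mass-driven and fraction densities are unknown; `mode = "equal_volume"`
#' splits by settled-volume shares instead (supply `volume_shares` when the
#' fractions' volume shares differ from their VS shares).
#'
#' @param state A [reactor_state()].
#' @param n_segments Number of CSTR segments (default 10).
#' @param duration_h Feeding duration used for the activation times
#'   (defaults to the reactor's feeding duration).
#' @param mode `"equal_vs"` (default) or `"equal_volume"`.
#' @param volume_shares Named settled-volume shares per fraction for
#'   `"equal_volume"` mode; defaults to the VS shares.
#' @return A list of class `bed_discretization` with the per-segment
#'   composition (g VS per fraction) and activation times.
#' @export
discretize_bed <- function(state, n_segments = 10,
                           duration_h = state$feeding_duration_h,
                           mode = c("equal_vs", "equal_volume"),
                           volume_shares = NULL) {
  mode <- match.arg(mode)
  n <- n_segments
  if (is.null(n) || n < 1) abort("n_segments must be >= 1")
  fr <- state$fractions |>
    dplyr::arrange(dplyr::desc(.data$size_min_um)) # settling order, bottom-up
  total_vs_g <- reactor_vs_kg(state) * 1000
  coord_shares <- fr$vs_share
  if (mode == "equal_volume") {
    vshare <- volume_shares %||% setNames(fr$vs_share, fr$fraction)
    if (!setequal(names(vshare), fr$fraction)) {
      abort("volume_shares must name every fraction")
    }
    coord_shares <- unname(vshare[fr$fraction]) / sum(vshare)
  }
  # cumulative-fill: fraction i occupies (lo_i, hi_i] of the bed coordinate;
  # segment j occupies ((j-1)/n, j/n]; overlap converts to VS mass
  hi <- cumsum(coord_shares)
  lo <- c(0, head(hi, -1))
  comp <- tidyr::expand_grid(segment = seq_len(n), i = seq_along(lo)) |>
    dplyr::mutate(
      seg_lo = (.data$segment - 1) / n,
      seg_hi = .data$segment / n,
      overlap = pmax(0, pmin(.data$seg_hi, hi[.data$i]) -
                       pmax(.data$seg_lo, lo[.data$i])),
      fraction = fr$fraction[.data$i],
      vs_g = dplyr::if_else(
        coord_shares[.data$i] > 0,
        .data$overlap / coord_shares[.data$i] * fr$vs_share[.data$i] * total_vs_g,
        0
      )
    ) |>
    dplyr::filter(.data$overlap > 0) |>
    dplyr::select("segment", "fraction", "vs_g")
  structure(
    list(
      n_segments = as.integer(n),
      duration_h = duration_h,
      total_vs_g = total_vs_g,
      composition = comp,
      activation_times_h = (seq_len(n) - 1) * duration_h / n,
      mode = mode
    ),
    class = "bed_discretization"
  )
}

#' @method tidy bed_discretization
#' @export
tidy.bed_discretization <- function(x, ...) {
  x$composition |>
    dplyr::mutate(
      activation_time_h = x$activation_times_h[.data$segment]
    )
}

#' @method glance bed_discretization
#' @export
glance.bed_discretization <- function(x, ...) {
  tibble::tibble(
    n_segments = x$n_segments,
    total_vs_kg = x$total_vs_g / 1000,
    duration_h = x$duration_h,
    mode = x$mode
  )
}

#' Maximum hydrolyzable substrate per litre of influent
#'
#' Tanks-in-series model of the anaerobic plug-flow feeding: the influent
#' fills the stratified bed bottom-up, each CSTR segment hydrolyzes at its
#' full zero-order rate from the moment the influent reaches it, and the
#' total dye-equivalent release over the feeding is converted to mg COD of
#' substrate and divided by the fed influent volume. Because the assays are
#' run at excess substrate, no depletion is modelled and the result is a
#' maximum capacity, not an in-situ rate.
#'
#' For a uniform bed the model reduces to the closed form
#' `k * M * T * (n + 1) / (2n) / V_f`.
#'
#' @param bed A [discretize_bed()] result.
#' @param activities Tibble with `fraction`, `enzyme_class`,
#'   `specific_activity` in umol dye (g VS h)^-1, covering every fraction in
#'   the bed. To apply one mixed-sludge activity bed-wide, list it for each
#'   fraction (see [activities_bed_wide()]).
#' @param scenario A [feeding_scenario()].
#' @param conversions A [conversion_table()].
#' @param assay Assay definitions; see [assay_definitions()].
#' @param state Needed only when the scenario includes bulk or influent
#'   activity terms (for the bulk volume and the activity maps).
#' @return A tibble of class `hydrolysis_capacity`: `enzyme_class`,
#'   `biomolecule`, `capacity_mg_cod_l`, with the scenario stored as an
#'   attribute.
#' @export
hydrolysis_capacity <- function(bed, activities,
                                scenario = feeding_scenario(),
                                conversions = conversion_table(),
                                assay = assay_definitions(),
                                state = NULL) {
  enz <- unique(activities$enzyme_class)
  active_time <- scenario$duration_h - scenario$duration_h *
    (seq_len(bed$n_segments) - 1) / bed$n_segments
  stopifnot(all(active_time > 0))
  contrib <- bed$composition |>
    dplyr::mutate(active_h = active_time[.data$segment]) |>
    tidyr::expand_grid(enzyme_class = enz) |>
    dplyr::left_join(
      dplyr::select(activities, "fraction", "enzyme_class", "specific_activity"),
      by = c("fraction", "enzyme_class")
    )
  if (any(is.na(contrib$specific_activity))) {
    miss <- unique(contrib$fraction[is.na(contrib$specific_activity)])
    abort(paste0("missing specific activity for bed fraction(s): ",
                 paste(miss, collapse = ", ")))
  }
  dye_umol <- contrib |>
    dplyr::group_by(.data$enzyme_class) |>
    dplyr::summarise(
      dye_umol = sum(.data$specific_activity * .data$vs_g * .data$active_h),
      .groups = "drop"
    )
  if (scenario$include_bulk_activity) {
    if (is.null(state) || is.null(state$bulk_activities)) {
      abort("bulk activity requested but no reactor state with bulk_activities")
    }
    vb_ml <- bulk_volume(state) * 1e6
    extra <- unname(state$bulk_activities[dye_umol$enzyme_class]) *
      vb_ml * scenario$duration_h
    dye_umol$dye_umol <- dye_umol$dye_umol + dplyr::coalesce(extra, 0)
  }
  if (scenario$include_influent_activity) {
    if (is.null(state) || is.null(state$influent_activities)) {
      abort("influent activity requested but no reactor state with influent_activities")
    }
    # parcels enter uniformly over the feeding, so mean exposure is T/2
    feed_ml <- scenario$feed_volume_m3 * 1e6
    extra <- unname(state$influent_activities[dye_umol$enzyme_class]) *
      feed_ml * scenario$duration_h / 2
    dye_umol$dye_umol <- dye_umol$dye_umol + dplyr::coalesce(extra, 0)
  }
  out <- dye_umol |>
    dplyr::mutate(
      biomolecule = assay$biomolecule[
        match(.data$enzyme_class, assay$enzyme_class)],
      capacity_mg_cod_l = dye_rate_to_cod_rate(
        .data$dye_umol, .data$enzyme_class, conversions, assay
      ) / (scenario$feed_volume_m3 * 1000)
    ) |>
    dplyr::select("enzyme_class", "biomolecule", "capacity_mg_cod_l")
  class(out) <- c("hydrolysis_capacity", class(out))
  attr(out, "scenario") <- scenario
  attr(out, "n_segments") <- bed$n_segments
  out
}

#' Replicate one activity set across all bed fractions
#'
#' Helper for applying mixed-sludge specific activities bed-wide when
#' per-fraction measurements are not available.
#'
#' @param specific_activities Named numeric: umol dye (g VS h)^-1 per enzyme
#'   class.
#' @param fractions Character vector of bed fractions (default the three
#'   solid bed fractions).
#' @return An activity tibble for [hydrolysis_capacity()].
#' @export
activities_bed_wide <- function(specific_activities,
                                fractions = c("large_granules",
                                              "small_granules", "flocs")) {
  tidyr::expand_grid(
    fraction = fractions,
    enzyme_class = names(specific_activities)
  ) |>
    dplyr::mutate(
      specific_activity = unname(specific_activities[.data$enzyme_class])
    )
}

#' Ratio of hydrolysis capacity to influent concentration
#'
#' mg COD/L and g COD/m^3 are numerically identical, so the ratio is the
#' factor by which the feeding-phase hydrolysis capacity exceeds the amount
#' of that substrate actually arriving with the influent.
#'
#' @param capacity_mg_cod_l Capacity in mg COD per L influent (vectorized).
#' @param influent_concentration_g_cod_m3 Influent concentration in
#'   g COD/m^3 (> 0).
#' @return Dimensionless overcapacity ratio.
#' @export
overcapacity_ratio <- function(capacity_mg_cod_l,
                               influent_concentration_g_cod_m3) {
  if (any(influent_concentration_g_cod_m3 <= 0)) {
    abort("influent concentration must be > 0")
  }
  capacity_mg_cod_l / influent_concentration_g_cod_m3
}

#' @method tidy hydrolysis_capacity
#' @export
tidy.hydrolysis_capacity <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @method glance hydrolysis_capacity
#' @export
glance.hydrolysis_capacity <- function(x, ...) {
  sc <- attr(x, "scenario")
  tibble::tibble(
    n_enzymes = nrow(x),
    n_segments = attr(x, "n_segments"),
    feed_volume_m3 = sc$feed_volume_m3,
    duration_h = sc$duration_h,
    total_capacity_mg_cod_l = sum(x$capacity_mg_cod_l)
  )
}
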