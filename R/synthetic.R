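#' Default ground-truth specific activities for synthetic campaigns
#'
#' Mixed-sludge magnitudes anchor the table (alpha-glucosidase 13,
#' beta-glucosidase 17, lipase 34, protease 10 umol (g VS h)^-1); the other
#' solid fractions scale them with the ordering reported for this sludge
#' (flocs > crushed granules > small granules > large granules). Bulk and
#' influent activities are per mL and much smaller.
#'
#' @return Tibble with `fraction`, `enzyme_class`, `specific_activity`.
#' @export
default_true_activities <- function() {
  mixed <- c(lipase = 34, alpha_glucosidase = 13,
             beta_glucosidase = 17, protease = 10)
  scale <- c(mixed = 1, large_granules = 0.85, crushed_granules = 1.7,
             small_granules = 1.3, flocs = 3)
  solids <- tidyr::expand_grid(
    fraction = names(scale),
    enzyme_class = names(mixed)
  ) |>
    dplyr::mutate(
      specific_activity = unname(mixed[.data$enzyme_class]) *
        unname(scale[.data$fraction])
    )
  liquids <- tibble::tribble(
    ~fraction, ~enzyme_class, ~specific_activity,
    "bulk", "lipase", 0.05,
    "bulk", "alpha_glucosidase", 0.01,
    "bulk", "beta_glucosidase", 0.01,
    "bulk", "protease", 0.02,
    "influent", "lipase", 0.02,
    "influent", "alpha_glucosidase", 0.03,
    "influent", "beta_glucosidase", 0.03,
    "influent", "protease", 0.01
  )
  dplyr::bind_rows(solids, liquids)
}

#' Specification of a synthetic assay campaign
#'
#' Describes a sampling campaign to simulate: by default 3 sampling days,
#' the 7 sample types, 4 enzyme assays and triplicate vials with 6 time
#' points each. Absorbance traces follow zero-order kinetics (linear product
#' release) with i.i.d. Gaussian absorbance noise; a small probability of a
#' failed replicate produces a flat noisy trace that the QC filter should
#' discard. Day-to-day variability multiplies the true activities by a
#' lognormal factor with the given coefficient of variation.
#'
#' @param n_days Number of sampling days (default 3).
#' @param fractions Sample types (default all 7).
#' @param enzymes Enzyme classes (default all 4).
#' @param n_replicates Replicates per vial condition (default 3).
#' @param n_timepoints Readings per trace (default 6).
#' @param true_activities Ground-truth specific activities; see
#'   [default_true_activities()].
#' @param day_cv Day-to-day coefficient of variation of the true activities
#'   (default 0.2).
#' @param noise_sd Absorbance noise standard deviation in AU (default 0.01).
#' @param fail_prob Probability that a replicate fails flat (default 0.05).
#' @param seed Integer seed fixing the whole output stream.
#' @param vial_volume_ml Vial working volume (default 40 mL).
#' @param biomass_g_vs_per_l Solid-fraction biomass concentration in the vial
#'   (default 4 g VS/L).
#' @param blank_au t0 blank absorbance (default 0.05 AU).
#' @return A list of class `campaign_spec`.
#' @export
campaign_spec <- function(n_days = 3,
                          fractions = sludge_fractions(),
                          enzymes = enzyme_classes(),
                          n_replicates = 3,
                          n_timepoints = 6,
                          true_activities = default_true_activities(),
                          day_cv = 0.2,
                          noise_sd = 0.01,
                          fail_prob = 0.05,
                          seed = 1L,
                          vial_volume_ml = 40,
                          biomass_g_vs_per_l = 4,
                          blank_au = 0.05) {
  if (n_days < 1 || n_replicates < 1 || n_timepoints < 1) {
    abort("counts must be >= 1")
  }
  if (fail_prob < 0 || fail_prob > 1) abort("fail_prob must be in [0, 1]")
  if (noise_sd < 0 || day_cv < 0) abort("noise_sd and day_cv must be >= 0")
  if (vial_volume_ml <= 0 || biomass_g_vs_per_l <= 0) {
    abort("vial volume and biomass concentration must be > 0")
  }
  structure(
    list(
      n_days = as.integer(n_days), fractions = fractions, enzymes = enzymes,
      n_replicates = as.integer(n_replicates),
      n_timepoints = as.integer(n_timepoints),
      true_activities = true_activities, day_cv = day_cv,
      noise_sd = noise_sd, fail_prob = fail_prob, seed = as.integer(seed),
      vial_volume_ml = vial_volume_ml,
      biomass_g_vs_per_l = biomass_g_vs_per_l, blank_au = blank_au
    ),
    class = "campaign_spec"
  )
}

#' Generate a synthetic assay campaign with known ground truth
#'
#' Inverts the measurement chain: a true specific activity times the assay
#' basis (g VS or mL in the vial) gives the vial dye-release rate; divided by
#' the vial volume and multiplied by the calibration slope it gives the
#' absorbance slope, from which noisy linear traces are sampled. Failed
#' replicates are emitted as flat noisy traces. With zero noise and zero
#' failure probability, re-fitting recovers the truth to machine precision.
#'
#' @param spec A [campaign_spec()].
#' @param calibration Calibration tibble (default [default_calibration()]).
#' @param assay Assay definitions (default [assay_definitions()]).
#' @return A list with `readings` (the raw absorbance table consumed by
#'   [fit_activities()]) and `truth` (one row per trace with the day-level
#'   true specific activity and the failure flag).
#' @export
generate_campaign <- function(spec, calibration = default_calibration(),
                              assay = assay_definitions()) {
  stopifnot(inherits(spec, "campaign_spec"))
  set.seed(spec$seed)
  basis <- assay_basis(spec$vial_volume_ml, spec$biomass_g_vs_per_l)
  sdlog <- sqrt(log(1 + spec$day_cv^2))
  calib_by_enzyme <- assay |>
    dplyr::left_join(dplyr::select(calibration, "dye", calib_slope = "slope"),
                     by = "dye")
  grid <- tidyr::expand_grid(
    day = seq_len(spec$n_days),
    fraction = spec$fractions,
    enzyme_class = spec$enzymes
  ) |>
    dplyr::left_join(spec$true_activities, by = c("fraction", "enzyme_class")) |>
    dplyr::left_join(dplyr::select(basis, "fraction", "basis_amount"),
                     by = "fraction") |>
    dplyr::left_join(
      dplyr::select(calib_by_enzyme, "enzyme_class", "assay_length_h",
                    "calib_slope"),
      by = "enzyme_class"
    )
  if (any(is.na(grid$specific_activity))) {
    abort("true_activities must cover every fraction x enzyme")
  }
  # day-level multipliers, mean 1
  grid$day_activity <- grid$specific_activity *
    rlnorm(nrow(grid), meanlog = -sdlog^2 / 2, sdlog = sdlog)

  truth <- grid |>
    tidyr::expand_grid(replicate = seq_len(spec$n_replicates)) |>
    dplyr::mutate(
      sample_id = sprintf("d%02d_%s", .data$day, .data$fraction),
      failed = stats::runif(dplyr::n()) < spec$fail_prob,
      slope_au_h = dplyr::if_else(
        .data$failed, 0,
        .data$day_activity * .data$basis_amount / spec$vial_volume_ml *
          .data$calib_slope
      )
    )
  readings <- truth |>
    tidyr::expand_grid(point = seq_len(spec$n_timepoints)) |>
    dplyr::mutate(
      time_h = if (spec$n_timepoints == 1) 0 else
        (.data$point - 1) / (spec$n_timepoints - 1) * .data$assay_length_h,
      absorbance = spec$blank_au + .data$slope_au_h * .data$time_h +
        rnorm(dplyr::n(), 0, spec$noise_sd)
    ) |>
    dplyr::select("sample_id", "day", "fraction", "enzyme_class",
                  "replicate", "time_h", "absorbance")
  truth <- truth |>
    dplyr::select("sample_id", "day", "fraction", "enzyme_class",
                  "replicate", true_specific_activity = "day_activity",
                  "failed", "basis_amount", "slope_au_h")
  list(readings = readings, truth = truth)
}

#' Recover specific activities from a generated campaign
#'
#' Runs the forward measurement chain (fit, calibrate, aggregate replicates
#' per sampling day, divide by the assay basis) on the readings of a
#' synthetic campaign, with the campaign's own vial volume and biomass basis.
#'
#' @param readings Readings tibble from [generate_campaign()].
#' @param spec The [campaign_spec()] used to generate them.
#' @param calibration Calibration tibble used at generation.
#' @return Aggregated tibble with `specific_activity` per
#'   `sample_id x fraction x enzyme_class`.
#' @export
recover_campaign <- function(readings, spec,
                             calibration = default_calibration()) {
  readings |>
    fit_activities() |>
    calibrate_rates(calibration, vial_volume_ml = spec$vial_volume_ml) |>
    aggregate_replicates() |>
    add_specific_activity(
      assay_basis(spec$vial_volume_ml, spec$biomass_g_vs_per_l)
    )
}

#' Generate a synthetic influent composition table
#'
#' Day-to-day variation is lognormal (mean-preserving) around the base
#' composition; soluble concentrations are derived as the base soluble/total
#' share of the sampled total, so soluble never exceeds total by
#' construction. `cv = 0` reproduces the base composition on every day.
#'
#' @param n_days Number of days.
#' @param base One-row tibble of base concentrations (default: the campaign
#'   average of the shipped influent table).
#' @param cv Day-to-day coefficient of variation (default 0.3).
#' @param seed Integer seed.
#' @return An influent tibble; see [read_influent()] for the dialect.
#' @export
generate_influent_table <- function(n_days,
                                    base = campaign_average(influent_campaign()),
                                    cv = 0.3, seed = 1L) {
  if (cv < 0) abort("cv must be >= 0")
  set.seed(as.integer(seed))
  sdlog <- sqrt(log(1 + cv^2))
  pairs <- influent_pairs()
  indep <- setdiff(influent_analytes(), pairs$soluble)
  rows <- purrr::map(seq_len(n_days), function(d) {
    row <- list(date = sprintf("day%03d", d), weather = "DWF")
    for (a in indep) {
      b <- base[[a]]
      row[[a]] <- if (is.na(b)) NA_real_ else
        b * rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    }
    for (i in seq_len(nrow(pairs))) {
      s <- base[[pairs$soluble[i]]]; t <- base[[pairs$total[i]]]
      share <- if (is.na(s) || is.na(t) || t == 0) 0 else s / t
      row[[pairs$soluble[i]]] <- row[[pairs$total[i]]] * share
    }
    tibble::as_tibble_row(row)
  })
  validate_influent(dplyr::bind_rows(rows))
}
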