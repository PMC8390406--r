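#' Read raw assay absorbance readings from CSV
#'
#' One row per spectrophotometer reading:
#' `sample_id, fraction, enzyme_class, replicate, time_h, absorbance`.
#'
#' @param path Path to the readings CSV (UTF-8, header required).
#' @return A tibble of readings, validated.
#' @export
read_assay_readings <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  validate_readings(x)
}

validate_readings <- function(x) {
  required <- c("sample_id", "fraction", "enzyme_class", "replicate",
                "time_h", "absorbance")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    abort(paste0("assay readings miss column(s): ",
                 paste(missing, collapse = ", ")))
  }
  bad_enz <- setdiff(unique(x$enzyme_class), enzyme_classes())
  if (length(bad_enz) > 0) {
    abort(paste0("unknown enzyme class: ", paste(bad_enz, collapse = ", ")))
  }
  if (any(!is.finite(x$absorbance))) abort("non-finite absorbance values")
  if (any(x$time_h < 0)) abort("negative assay times")
  tibble::as_tibble(x)
}

#' Fit zero-order product-release kinetics per replicate trace
#'
#' Ordinary least-squares regression of absorbance on time, with a free
#' intercept (the t0 blank varies between vials and is absorbed by the
#' intercept; the slope is invariant to blank subtraction). Each
#' `sample_id x fraction x enzyme_class x replicate` group yields one row.
#'
#' Traces are flagged `qc_pass = FALSE` when the coefficient of determination
#' falls below `r2_min` or fewer than `min_points` readings are available;
#' boundary values (R-squared exactly at `r2_min`, exactly `min_points`
#' readings) pass. Failed traces keep their fitted slope for inspection but
#' are excluded from downstream aggregation.
#'
#' @param readings Tibble of raw readings; see [read_assay_readings()].
#' @param r2_min Minimum coefficient of determination (default 0.7).
#' @param min_points Minimum number of time points (default 4).
#' @return A tibble of class `activity_fits`: one row per trace with `slope`
#'   (AU/h), `intercept`, `slope_se`, `r_squared`, `n_points`, `qc_pass`,
#'   `qc_reason`.
#' @export
#' @examples
#' readings <- tibble::tibble(
#'   sample_id = "s1", fraction = "mixed", enzyme_class = "protease",
#'   replicate = 1L, time_h = c(0, 0.5, 1, 1.5), absorbance = 0.1 + 0.2 * c(0, 0.5, 1, 1.5)
#' )
#' fit_activities(readings)
fit_activities <- function(readings, r2_min = 0.7, min_points = 4) {
  readings <- validate_readings(readings)
  # closed-form OLS sufficient statistics per trace, fully vectorized
  fits <- readings |>
    dplyr::group_by(.data$sample_id, .data$fraction, .data$enzyme_class,
                    .data$replicate) |>
    dplyr::arrange(.data$time_h, .by_group = TRUE) |>
    dplyr::summarise(
      n_points = dplyr::n(),
      unique_times = dplyr::n() < 2 || all(diff(.data$time_h) > 0),
      sxx = sum((.data$time_h - mean(.data$time_h))^2),
      sxy = sum((.data$time_h - mean(.data$time_h)) *
                  (.data$absorbance - mean(.data$absorbance))),
      sst = sum((.data$absorbance - mean(.data$absorbance))^2),
      mx = mean(.data$time_h),
      my = mean(.data$absorbance),
      .groups = "drop"
    )
  if (!all(fits$unique_times)) abort("times must be strictly increasing")
  if (any(fits$n_points >= 2 & fits$sxx == 0)) abort("degenerate time axis")
  fits <- fits |>
    dplyr::mutate(
      slope = dplyr::if_else(.data$n_points >= 2, .data$sxy / .data$sxx,
                             NA_real_),
      intercept = .data$my - .data$slope * .data$mx,
      sse = pmax(0, .data$sst - .data$slope^2 * .data$sxx),
      # a zero-variance (flat) trace carries no detectable signal: R2 = 0
      r_squared = dplyr::case_when(
        .data$n_points < 2 ~ NA_real_,
        .data$sst == 0 ~ 0,
        TRUE ~ 1 - .data$sse / .data$sst
      ),
      slope_se = dplyr::if_else(
        .data$n_points > 2,
        sqrt(.data$sse / (.data$n_points - 2) / .data$sxx),
        NA_real_
      ),
      qc_reason = dplyr::case_when(
        .data$n_points < 2 ~ "insufficient points",
        .data$n_points < min_points & .data$r_squared < r2_min ~
          sprintf("n_points < %d; R2 < %s", min_points, format(r2_min)),
        .data$n_points < min_points ~ sprintf("n_points < %d", min_points),
        .data$r_squared < r2_min ~ sprintf("R2 < %s", format(r2_min)),
        TRUE ~ ""
      ),
      qc_pass = .data$qc_reason == ""
    ) |>
    dplyr::select("sample_id", "fraction", "enzyme_class", "replicate",
                  "n_points", "slope", "intercept", "slope_se",
                  "r_squared", "qc_pass", "qc_reason")
  class(fits) <- c("activity_fits", class(fits))
  attr(fits, "qc") <- list(r2_min = r2_min, min_points = min_points)
  fits
}

#' Convert a fitted slope to a dye-release rate
#'
#' The regression slope (AU/h) divided by the calibration slope
#' (AU per umol dye per mL) gives a volumetric dye concentration rate, which
#' multiplied by the vial working volume yields the total dye release rate of
#' the vial in umol/h. The calibration is assumed built on standards carried
#' through the same TCA/NaOH workup as the samples; set `dilution_factor` to
#' apply an explicit correction instead.
#'
#' @param reg One fitted trace: a one-row data frame or list with at least
#'   `slope` and `qc_pass`.
#' @param calib One calibration curve: a one-row data frame or list with a
#'   positive `slope`.
#' @param vial_volume_ml Vial working volume in mL (default 40).
#' @param dilution_factor Extra dilution correction (default 1).
#' @return Dye release rate in umol/h. Negative slopes on QC-passed traces are
#'   clamped to zero with a warning (released product cannot be consumed).
#' @export
to_dye_rate <- function(reg, calib, vial_volume_ml = 40, dilution_factor = 1) {
  if (!isTRUE(reg$qc_pass)) abort("below detection limit")
  if (calib$slope <= 0) abort("calibration slope must be > 0")
  if (vial_volume_ml <= 0) abort("vial volume must be > 0")
  rate <- reg$slope / calib$slope * vial_volume_ml * dilution_factor
  if (rate < 0) {
    warn("negative fitted rate clamped to zero")
    rate <- 0
  }
  rate
}

#' Calibrate fitted slopes into dye-release rates, table-wise
#'
#' Joins each fitted trace to the calibration curve of its assay dye and adds
#' `rate` and `rate_sd` in umol dye/h (vial totals). QC-failed traces get
#' `NA` rates and keep their flags. Negative rates on QC-passed traces are
#' clamped to zero with a warning.
#'
#' @param fits Output of [fit_activities()].
#' @param calibration Calibration tibble; see [default_calibration()].
#' @param vial_volume_ml Vial working volume in mL (default 40).
#' @param dilution_factor Extra dilution correction (default 1).
#' @return `fits` with `rate` and `rate_sd` columns added.
#' @export
calibrate_rates <- function(fits, calibration = default_calibration(),
                            vial_volume_ml = 40, dilution_factor = 1) {
  if (vial_volume_ml <= 0) abort("vial volume must be > 0")
  if (any(calibration$slope <= 0)) abort("calibration slope must be > 0")
  dye_map <- assay_definitions() |> dplyr::select("enzyme_class", "dye")
  out <- fits |>
    dplyr::left_join(dye_map, by = "enzyme_class") |>
    dplyr::left_join(
      dplyr::select(calibration, "dye", calib_slope = "slope"),
      by = "dye"
    )
  if (any(is.na(out$calib_slope))) {
    abort("no calibration curve for one or more assay dyes")
  }
  out <- out |>
    dplyr::mutate(
      rate = dplyr::if_else(
        .data$qc_pass,
        .data$slope / .data$calib_slope * vial_volume_ml * dilution_factor,
        NA_real_
      ),
      rate_sd = dplyr::if_else(
        .data$qc_pass,
        .data$slope_se / .data$calib_slope * vial_volume_ml * dilution_factor,
        NA_real_
      )
    )
  n_neg <- sum(out$rate < 0, na.rm = TRUE)
  if (n_neg > 0) {
    warn(sprintf("%d negative fitted rate(s) clamped to zero", n_neg))
    out$rate <- pmax(out$rate, 0)
  }
  dplyr::select(out, -"dye", -"calib_slope")
}

#' Combine replicate rates into a mean and an aggregated uncertainty
#'
#' The aggregated standard deviation combines the spread between replicates
#' with the uncertainty of the individual regression fits as a
#' root-sum-of-squares: `sqrt(var(rates) + mean(fit_sds^2))`. This is the one
#' place that interpretation lives, so it can be swapped.
#'
#' @param rates Numeric vector of QC-passed replicate rates.
#' @param fit_sds Numeric vector of per-fit rate standard errors (same
#'   length; `NA` treated as 0).
#' @return A list with `mean`, `sd` and `n`.
#' @export
#' @examples
#' aggregate_rates(c(3, 4, 5), c(0, 0, 0)) # sd 1
aggregate_rates <- function(rates, fit_sds = rep(0, length(rates))) {
  stopifnot(length(rates) == length(fit_sds))
  if (length(rates) == 0) abort("no QC-passed replicates: below detection")
  fit_sds[is.na(fit_sds)] <- 0
  between_var <- if (length(rates) > 1) var(rates) else 0
  list(
    mean = mean(rates),
    sd = sqrt(between_var + mean(fit_sds^2)),
    n = length(rates)
  )
}

#' Aggregate calibrated replicate rates per sample and enzyme
#'
#' QC-failed replicates are dropped before averaging. Groups with no passing
#' replicate are flagged `below_detection` with `NA` rates rather than
#' dropped, so the report keeps a complete sample inventory.
#'
#' @param rates Output of [calibrate_rates()].
#' @return One row per `sample_id x fraction x enzyme_class` with `rate`,
#'   `rate_sd`, `n_replicates`, `below_detection`.
#' @export
aggregate_replicates <- function(rates) {
  rates |>
    dplyr::group_by(.data$sample_id, .data$fraction, .data$enzyme_class) |>
    dplyr::group_modify(function(d, key) {
      ok <- d$qc_pass & !is.na(d$rate)
      if (!any(ok)) {
        return(tibble::tibble(
          rate = NA_real_, rate_sd = NA_real_,
          n_replicates = 0L, below_detection = TRUE
        ))
      }
      agg <- aggregate_rates(d$rate[ok], d$rate_sd[ok])
      tibble::tibble(
        rate = agg$mean, rate_sd = agg$sd,
        n_replicates = as.integer(agg$n), below_detection = FALSE
      )
    }) |>
    dplyr::ungroup()
}

#' Biomass- or volume-specific activity
#'
#' Divides a vial-total rate by the amount of biomass (g VS) or sample volume
#' (mL) used in the assay.
#'
#' @param rate Rate in umol dye/h.
#' @param basis_amount Biomass (g VS) or volume (mL) in the vial; must be > 0.
#' @return Specific activity in umol dye (g VS h)^-1 or umol dye (mL h)^-1.
#' @export
specific_activity <- function(rate, basis_amount) {
  if (any(basis_amount <= 0)) abort("basis amount must be > 0")
  rate / basis_amount
}

#' Default per-fraction assay basis
#'
#' Solid sludge fractions are assayed at a standard biomass concentration
#' (default 4 g VS/L of vial volume) and expressed per g VS; bulk liquid and
#' influent are assayed as-is and expressed per mL.
#'
#' @param vial_volume_ml Vial working volume in mL (default 40).
#' @param biomass_g_vs_per_l Biomass concentration of solid-fraction assays in
#'   g VS/L (default 4).
#' @return Tibble with `fraction`, `basis`, `basis_amount`.
#' @export
assay_basis <- function(vial_volume_ml = 40, biomass_g_vs_per_l = 4) {
  fr <- sludge_fractions()
  liquid <- fr %in% liquid_fractions()
  tibble::tibble(
    fraction = fr,
    basis = ifelse(liquid, "per_mL", "per_gVS"),
    basis_amount = ifelse(liquid, vial_volume_ml,
                          biomass_g_vs_per_l * vial_volume_ml / 1000)
  )
}

#' Add specific activities to an aggregated rate table
#'
#' @param rates Output of [aggregate_replicates()].
#' @param basis Tibble mapping `fraction` to `basis` and `basis_amount`; see
#'   [assay_basis()].
#' @return `rates` with `basis`, `basis_amount`, `specific_activity`,
#'   `specific_sd` columns.
#' @export
add_specific_activity <- function(rates, basis = assay_basis()) {
  out <- dplyr::left_join(rates, basis, by = "fraction")
  if (any(is.na(out$basis_amount))) {
    abort("no assay basis for one or more fractions")
  }
  if (any(out$basis_amount <= 0)) abort("basis amount must be > 0")
  out |>
    dplyr::mutate(
      specific_activity = .data$rate / .data$basis_amount,
      specific_sd = .data$rate_sd / .data$basis_amount
    )
}

#' @method glance activity_fits
#' @export
glance.activity_fits <- function(x, ...) {
  qc <- attr(x, "qc") %||% list(r2_min = NA_real_, min_points = NA_integer_)
  tibble::tibble(
    n_traces = nrow(x),
    n_pass = sum(x$qc_pass),
    pass_rate = mean(x$qc_pass),
    median_r_squared = stats::median(x$r_squared, na.rm = TRUE),
    r2_min = qc$r2_min,
    min_points = qc$min_points
  )
}
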