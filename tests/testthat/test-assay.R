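test_that("exact linear data recovers the generating slope with R2 = 1", {
  t <- c(0, 0.25, 0.5, 0.75, 1.0)
  r <- fit_activities(make_readings(t, 0.10 + 0.20 * t))
  expect_equal(r$slope, 0.20)
  expect_equal(r$intercept, 0.10)
  expect_equal(r$r_squared, 1)
  expect_true(r$qc_pass)
  expect_equal(r$n_points, 5L)
})

test_that("short series are rejected but keep their slope", {
  t <- c(0, 0.5, 1)
  r <- fit_activities(make_readings(t, 0.1 + 0.2 * t))
  expect_false(r$qc_pass)
  expect_equal(r$qc_reason, "n_points < 4")
  expect_equal(r$slope, 0.2)

  r1 <- fit_activities(make_readings(0.5, 0.3))
  expect_false(r1$qc_pass)
  expect_equal(r1$qc_reason, "insufficient points")
  expect_true(is.na(r1$slope))
})

test_that("a flat noisy trace fails the R2 filter, matching an independent OLS oracle", {
  tr <- flat_noisy_trace()
  orc <- oracle_ols(tr$times, tr$absorbance)
  expect_lt(orc$r2, 0.7)
  r <- fit_activities(make_readings(tr$times, tr$absorbance))
  expect_equal(r$r_squared, orc$r2)
  expect_equal(r$slope, orc$slope)
  expect_false(r$qc_pass)
  expect_match(r$qc_reason, "R2 < 0.7")
})

test_that("QC passes exactly at both thresholds and fails just below them", {
  # R^2 exactly 0.7 with 4 points: both boundaries at once
  tr <- boundary_r2_trace()
  r <- fit_activities(make_readings(tr$times, tr$absorbance))
  expect_equal(r$r_squared, 0.7)
  expect_equal(r$n_points, 4L)
  expect_true(r$qc_pass)

  # inflate the residual pattern: R^2 drops below 0.7, discarded
  y_bad <- c(0, 1, 2, 5) + 1.2 * c(1, -2, 1, 0)
  r_bad <- fit_activities(make_readings(tr$times, y_bad))
  expect_lt(r_bad$r_squared, 0.7)
  expect_false(r_bad$qc_pass)

  # 4 exact-linear points pass, 3 are discarded
  expect_true(fit_activities(make_readings(0:3, 1 + 0:3))$qc_pass)
  expect_false(fit_activities(make_readings(0:2, 1 + 0:2))$qc_pass)
})

test_that("degenerate and malformed time axes error", {
  expect_error(fit_activities(make_readings(c(1, 1, 1), c(1, 2, 3))),
               "strictly increasing|degenerate")
  expect_error(
    fit_activities(make_readings(c(0, 0.5, 0.5, 1), c(1, 2, 2, 3))),
    "strictly increasing"
  )
})

test_that("dye-rate conversion is slope / calibration x vial volume", {
  reg <- list(slope = 0.20, qc_pass = TRUE)
  expect_equal(to_dye_rate(reg, list(slope = 2.0), 40), 4.0)
  expect_equal(to_dye_rate(list(slope = 0, qc_pass = TRUE), list(slope = 2), 40), 0)
  expect_equal(to_dye_rate(list(slope = 0.0725, qc_pass = TRUE),
                           list(slope = 1.45), 30), 1.5)
  expect_error(to_dye_rate(list(slope = 0.2, qc_pass = FALSE), list(slope = 2)),
               "below detection limit")
  expect_warning(
    out <- to_dye_rate(list(slope = -0.1, qc_pass = TRUE), list(slope = 2), 40),
    "clamped"
  )
  expect_equal(out, 0)
})

test_that("replicate aggregation combines spread and fit uncertainty", {
  a <- aggregate_rates(c(4, 4, 4), c(0, 0, 0))
  expect_equal(a$mean, 4)
  expect_equal(a$sd, 0)

  b <- aggregate_rates(c(3, 4, 5), c(0, 0, 0))
  expect_equal(b$mean, 4)
  expect_equal(b$sd, 1) # sample SD oracle

  c2 <- aggregate_rates(c(4, 4), c(0.3, 0.4))
  expect_equal(c2$mean, 4)
  expect_equal(c2$sd, sqrt((0.09 + 0.16) / 2))

  expect_error(aggregate_rates(numeric(0)), "below detection")
})

test_that("replicate aggregation is permutation invariant", {
  set.seed(42)
  for (i in 1:20) {
    r <- stats::runif(5, 0, 10)
    s <- stats::runif(5, 0, 1)
    p <- sample(5)
    a <- aggregate_rates(r, s)
    b <- aggregate_rates(r[p], s[p])
    expect_equal(a$mean, b$mean)
    expect_equal(a$sd, b$sd)
  }
})

test_that("table-wise aggregation drops QC failures and flags empty groups", {
  t <- c(0, 0.25, 0.5, 0.75, 1.0, 1.25)
  flat <- flat_noisy_trace()
  readings <- dplyr::bind_rows(
    make_readings(t, 0.1 + 0.2 * t, replicate = 1L),
    make_readings(t, 0.1 + 0.3 * t, replicate = 2L),
    make_readings(flat$times, flat$absorbance, replicate = 3L),
    make_readings(flat$times, flat$absorbance, sample_id = "dead")
  )
  agg <- readings |>
    fit_activities() |>
    calibrate_rates(tibble::tibble(dye = "azo_dye", slope = 0.5,
                                   intercept = 0, range_lo = 0, range_hi = 3),
                    vial_volume_ml = 40) |>
    aggregate_replicates()
  s1 <- agg[agg$sample_id == "s1", ]
  expect_equal(s1$n_replicates, 2L)
  expect_equal(s1$rate, mean(c(0.2, 0.3) / 0.5 * 40))
  dead <- agg[agg$sample_id == "dead", ]
  expect_true(dead$below_detection)
  expect_true(is.na(dead$rate))
})

test_that("specific activity scales as rate over basis", {
  expect_equal(specific_activity(4.0, 0.16), 25)
  expect_equal(specific_activity(0, 2), 0)
  expect_equal(specific_activity(1.2, 40), 0.03)
  expect_error(specific_activity(1, 0), "> 0")
  # homogeneity: degree +1 in rate, -1 in basis
  expect_equal(specific_activity(3 * 1.2, 40), 3 * specific_activity(1.2, 40))
  expect_equal(specific_activity(1.2, 2 * 40), specific_activity(1.2, 40) / 2)
})
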