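test_that("cumulative fill allocates the stratified bed as expected", {
  st <- uniform_state()
  # single fraction: every segment pure large granules
  st1 <- st
  st1$fractions <- granule_fractions(c(large_granules = 1,
                                       small_granules = 0, flocs = 0))
  bed1 <- discretize_bed(st1, 10)
  expect_setequal(unique(bed1$composition$fraction), "large_granules")
  expect_equal(nrow(bed1$composition), 10)

  # default shares (0.84, 0.07, 0.09): segments 1-8 pure large,
  # segment 9 mixes large and small, segment 10 small and flocs
  bed <- discretize_bed(st, 10)
  comp <- tidyr::pivot_wider(bed$composition, names_from = "fraction",
                             values_from = "vs_g", values_fill = 0)
  tot <- bed$total_vs_g
  for (j in 1:8) {
    expect_equal(comp$large_granules[comp$segment == j], 0.1 * tot)
  }
  expect_equal(comp$large_granules[comp$segment == 9], 0.04 * tot)
  expect_equal(comp$small_granules[comp$segment == 9], 0.06 * tot)
  expect_equal(comp$small_granules[comp$segment == 10], 0.01 * tot)
  expect_equal(comp$flocs[comp$segment == 10], 0.09 * tot)
  # segment masses conserve the bed total
  expect_equal(sum(bed$composition$vs_g), tot, tolerance = 1e-9)

  # n = 1: one fully mixed segment active from t = 0
  b1 <- discretize_bed(st, 1)
  expect_equal(b1$activation_times_h, 0)
  expect_equal(sort(unique(b1$composition$fraction)),
               c("flocs", "large_granules", "small_granules"))

  expect_error(discretize_bed(st, 0), ">= 1")
})

test_that("activation times rise linearly from the bottom segment", {
  bed <- discretize_bed(uniform_state(), 10, duration_h = 1)
  expect_equal(bed$activation_times_h, (0:9) / 10)
  expect_true(all(diff(bed$activation_times_h) >= 0))
})

test_that("uniform-bed capacity matches the closed form for n in {1, 2, 10, 100}", {
  st <- uniform_state(vs_kg = 1000, feed_m3 = 1000)
  a <- 7.3 # umol (g VS h)^-1
  k <- dye_rate_to_cod_rate(a, "alpha_glucosidase") # g COD (kg VS h)^-1
  for (n in c(1, 2, 10, 100)) {
    bed <- discretize_bed(st, n)
    cap <- hydrolysis_capacity(bed, uniform_activities(a),
                               feeding_scenario(feed_volume_m3 = 1000,
                                                duration_h = 1))
    expect_equal(cap$capacity_mg_cod_l,
                 closed_form_capacity(k, 1000, 1, n, 1000),
                 tolerance = 1e-9)
  }
})

test_that("the exposure factor tends to 1/2 as the cascade refines", {
  st <- uniform_state()
  a <- 5
  bed <- discretize_bed(st, 1000)
  cap <- hydrolysis_capacity(bed, uniform_activities(a),
                             feeding_scenario(feed_volume_m3 = 1000))
  cap1 <- hydrolysis_capacity(discretize_bed(st, 1), uniform_activities(a),
                              feeding_scenario(feed_volume_m3 = 1000))
  expect_lt(abs(cap$capacity_mg_cod_l / cap1$capacity_mg_cod_l - 0.5), 1e-3)
})

test_that("capacity is linear in activities and additive over fractions", {
  st <- uniform_state()
  bed <- discretize_bed(st, 10)
  sc <- feeding_scenario(feed_volume_m3 = 1000)
  acts <- tibble::tibble(
    fraction = c("large_granules", "small_granules", "flocs"),
    enzyme_class = "protease",
    specific_activity = c(2, 4, 6)
  )
  c1 <- hydrolysis_capacity(bed, acts, sc)$capacity_mg_cod_l
  c2 <- hydrolysis_capacity(
    bed, dplyr::mutate(acts, specific_activity = 3 * specific_activity), sc
  )$capacity_mg_cod_l
  expect_equal(c2, 3 * c1)
  # row order of the activity table is irrelevant
  c3 <- hydrolysis_capacity(bed, acts[c(3, 1, 2), ], sc)$capacity_mg_cod_l
  expect_equal(c3, c1)
  # longer feeding at fixed volume hydrolyzes no less
  c4 <- hydrolysis_capacity(
    bed, acts, feeding_scenario(feed_volume_m3 = 1000, duration_h = 2)
  )$capacity_mg_cod_l
  expect_gte(c4, c1)
  # zero activities give zero capacity
  c0 <- hydrolysis_capacity(
    bed, dplyr::mutate(acts, specific_activity = 0), sc)$capacity_mg_cod_l
  expect_equal(c0, 0)
  # a missing bed fraction is an error
  expect_error(hydrolysis_capacity(bed, acts[1:2, ], sc),
               "missing specific activity")
})

test_that("overcapacity ratio divides capacity by influent concentration", {
  expect_equal(overcapacity_ratio(570, 12.7), 570 / 12.7)
  expect_equal(round(overcapacity_ratio(570, 12.7)), 45)
  expect_equal(overcapacity_ratio(33, 33), 1)
  expect_equal(overcapacity_ratio(240, 10), 24)
  expect_error(overcapacity_ratio(100, 0), "> 0")
})

test_that("tidy and glance expose the capacity and bed summaries", {
  st <- uniform_state()
  bed <- discretize_bed(st, 10)
  td <- tidy(bed)
  expect_true(all(c("segment", "fraction", "vs_g", "activation_time_h") %in%
                    names(td)))
  cap <- hydrolysis_capacity(bed, uniform_activities(2),
                             feeding_scenario(feed_volume_m3 = 1000))
  expect_s3_class(tidy(cap), "tbl_df")
  gl <- glance(cap)
  expect_equal(gl$n_segments, 10L)
  expect_equal(gl$feed_volume_m3, 1000)
})
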