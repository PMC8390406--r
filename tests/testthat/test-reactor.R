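test_that("bulk volume follows the settled-sludge equation", {
  st <- reactor_state(9500, 13.5, 0.8, svi30_ml_g = 40, bed_porosity = 0.52,
                      feed_batch_m3 = 3870)
  expect_equal(bulk_volume(st), 9500 * (1 - 0.54 * 0.48)) # 7037.6
  # limits: vanishing solids or fully porous bed leave the whole reactor as bulk
  st0 <- reactor_state(9500, 1e-9, 0.8, svi30_ml_g = 40, feed_batch_m3 = 3870)
  expect_equal(bulk_volume(st0), 9500, tolerance = 1e-6)
  st1 <- reactor_state(9500, 13.5, 0.8, svi30_ml_g = 40,
                       bed_porosity = 1 - 1e-12, feed_batch_m3 = 3870)
  expect_equal(bulk_volume(st1), 9500, tolerance = 1e-6)
  # overfull reactor errors
  st_bad <- reactor_state(9500, 60, 0.8, svi30_ml_g = 40, bed_porosity = 0.52,
                          feed_batch_m3 = 3870)
  expect_error(bulk_volume(st_bad), "exceeds reactor")
})

test_that("bulk volume is monotone in TS, SVI and porosity", {
  mk <- function(ts = 13.5, svi = 40, eps = 0.52) {
    bulk_volume(reactor_state(9500, ts, 0.8, svi30_ml_g = svi,
                              bed_porosity = eps, feed_batch_m3 = 3870))
  }
  expect_lt(mk(ts = 15), mk(ts = 12))
  expect_lt(mk(svi = 45), mk(svi = 35))
  expect_gt(mk(eps = 0.6), mk(eps = 0.4))
})

test_that("reactor-level activity scales specific activities by VS inventory", {
  st1 <- reactor_state(1, 1, 1, svi30_ml_g = 40, feed_batch_m3 = 1,
                       fractions = granule_fractions(c(large_granules = 1,
                                                       small_granules = 0,
                                                       flocs = 0)))
  acts <- tibble::tibble(fraction = "large_granules",
                         enzyme_class = "protease", specific_activity = 1)
  br <- reactor_level_activity(st1, acts)
  expect_equal(br$activity_umol_h[br$source == "large_granules"], 1000)

  st2 <- reactor_state(1, 100, 1, svi30_ml_g = 1, feed_batch_m3 = 1)
  acts2 <- tibble::tibble(
    fraction = c("large_granules", "small_granules", "flocs"),
    enzyme_class = "protease",
    specific_activity = c(1, 2, 3)
  )
  br2 <- reactor_level_activity(st2, acts2)
  expect_equal(sum(br2$activity_umol_h), 84000 + 14000 + 27000)

  br0 <- reactor_level_activity(st2, dplyr::mutate(acts2, specific_activity = 0))
  expect_equal(sum(br0$activity_umol_h), 0)

  expect_error(reactor_level_activity(st2, acts2[1:2, ]),
               "missing specific activity")
})

test_that("activity shares are percentages summing to 100", {
  st <- reactor_state(1, 100, 1, svi30_ml_g = 1, feed_batch_m3 = 1)
  acts <- tibble::tibble(
    fraction = c("large_granules", "small_granules", "flocs"),
    enzyme_class = "protease", specific_activity = c(1, 2, 3)
  )
  br <- activity_shares(reactor_level_activity(st, acts))
  expect_equal(sum(br$share_pct), 100, tolerance = 1e-9)
  expect_equal(br$share_pct[br$source == "large_granules"], 67.2)

  # invariant under uniform rescaling
  br2 <- activity_shares(reactor_level_activity(
    st, dplyr::mutate(acts, specific_activity = specific_activity * 17)))
  expect_equal(br$share_pct, br2$share_pct)

  # four equal sources split 25 % each; a single source takes 100 %
  eq <- tibble::tibble(enzyme_class = "lipase",
                       source = c("a", "b", "c", "d"),
                       activity_umol_h = 3)
  expect_equal(activity_shares(eq)$share_pct, rep(25, 4))
  one <- tibble::tibble(enzyme_class = "lipase", source = "a",
                        activity_umol_h = 7)
  expect_equal(activity_shares(one)$share_pct, 100)

  expect_error(
    activity_shares(reactor_level_activity(
      st, dplyr::mutate(acts, specific_activity = 0))),
    "zero"
  )
})

test_that("loading rates reproduce the plant descriptors", {
  st <- garmerwolde_reactor()
  lr <- loading_rates(st, 15500, 619)
  expect_equal(round(lr$volumetric_loading, 1), 1.6)
  expect_equal(round(lr$sludge_loading, 2), 0.07)
  expect_equal(round(lr$ver_pct), 41)
  # VER and volumetric loading do not depend on TS
  st2 <- garmerwolde_reactor(); st2$ts_g_l <- 20
  lr2 <- loading_rates(st2, 15500, 619)
  expect_equal(lr2$volumetric_loading, lr$volumetric_loading)
  expect_equal(lr2$ver_pct, lr$ver_pct)
  expect_false(isTRUE(all.equal(lr2$sludge_loading, lr$sludge_loading)))
  # zero flow
  lr0 <- loading_rates(st, 0, 619)
  expect_equal(lr0$volumetric_loading, 0)
  expect_equal(lr0$sludge_loading, 0)
})

test_that("sphere-equivalent volume is pi/6 d^3", {
  expect_equal(sphere_equivalent_volume(0), 0)
  expect_equal(sphere_equivalent_volume(1), pi / 6)
  expect_equal(sphere_equivalent_volume(3.6), pi / 6 * 3.6^3)
  expect_equal(round(sphere_equivalent_volume(3.6), 2), 24.43)
  expect_error(sphere_equivalent_volume(-1), ">= 0")
})

test_that("fraction composition validates shares and size ranges", {
  fr <- granule_fractions()
  expect_equal(sum(fr$vs_share), 1)
  # non-overlapping size ranges
  fr <- fr[order(fr$size_min_um), ]
  expect_true(all(fr$size_max_um[-nrow(fr)] <= fr$size_min_um[-1]))
  expect_error(granule_fractions(c(large_granules = 0.8,
                                   small_granules = 0.1, flocs = 0.2)),
               "sum to 1")
})
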