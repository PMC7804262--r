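test_that("amplitude thresholding keeps or prunes a single sine period", {
  x <- seq(0, 60, length.out = 121)
  p <- make_profile(x, 2 * sin(2 * pi * x / 60))
  ps <- find_extrema(p, min_amplitude = 1)
  expect_equal(nrow(ps$maxima), 1)
  expect_equal(nrow(ps$minima), 1)
  expect_equal(ps$maxima$elevation, 2, tolerance = 1e-3)

  ps5 <- find_extrema(p, min_amplitude = 5)
  expect_equal(nrow(ps5$extrema), 0)
})

test_that("a deep trough in shallow ripple keeps only the trough and its shoulders", {
  x <- seq(0, 600, by = 1)
  ripple <- 0.5 * cos(2 * pi * x / 60)  # 1 um peak-to-trough
  trough <- -30 * exp(-(x - 300)^2 / (2 * 30^2))
  p <- make_profile(x, ripple + trough)
  ps <- find_extrema(p, min_amplitude = 5)
  expect_equal(nrow(ps$minima), 1)
  expect_lt(abs(ps$minima$distance - 300), 2)
  # the occlusal shoulder is retained; the ripple never swings past the
  # threshold so no other extremum survives
  expect_equal(nrow(ps$maxima), 1)
  expect_lt(ps$maxima$distance, 300)
  # agreement with the naive segment-rescan oracle
  or <- oracle_find_extrema(p, 5)
  expect_equal(ps$extrema$distance, or$distance)
  expect_equal(ps$extrema$elevation, or$elevation)
})

test_that("plateaus collapse to single midpoint extrema", {
  x <- 0:11
  z <- c(0, 1, 2, 2, 2, 1, 0, -1, -1, 0, 1, 2)
  p <- make_profile(x, z)
  ps <- find_extrema(p, min_amplitude = 0)
  expect_equal(nrow(ps$maxima), 1)
  expect_equal(ps$maxima$distance, 3)   # plateau 2,3,4 -> midpoint 3
  expect_equal(nrow(ps$minima), 1)
  expect_equal(ps$minima$distance, 7.5) # plateau 7,8 -> midpoint 7.5
})

test_that("retained extrema alternate and all adjacent spans respect the threshold", {
  withr::local_seed(77)
  for (rep in 1:50) {
    p <- random_profile(sample(8:200, 1), quantize = rep %% 2 == 0)
    thr <- runif(1, 0, 4)
    ps <- find_extrema(p, thr)
    ext <- ps$extrema
    if (nrow(ext) >= 2) {
      expect_true(all(ext$type[-1] != ext$type[-nrow(ext)]))
      expect_true(all(abs(diff(ext$elevation)) >= thr))
    }
    # monotonicity: a higher threshold never retains more extrema
    ps2 <- find_extrema(p, thr + 1)
    expect_lte(nrow(ps2$extrema), nrow(ext))
  }
})

test_that("defect depth follows the occlusal-shoulder convention", {
  # shoulders at 50 um flanking a floor at 20 um
  x <- seq(0, 200, by = 1)
  z <- 50 - 30 * exp(-(x - 100)^2 / (2 * 20^2)) + 0.3 * cos(2 * pi * x / 40)
  m <- measure_defect_depth(make_profile(x, z), min_amplitude = 5)
  expect_equal(m$feature_kind, "defect")
  expect_equal(m$depth_um, 50.3 - min(z), tolerance = 0.05)
  expect_lt(m$shoulder_distance, m$floor_distance)
  expect_gt(m$cervical_shoulder_distance, m$floor_distance)

  # monotone ramp: no interior minimum
  expect_error(measure_defect_depth(make_profile(x, 0.1 * x)),
               class = "ed_no_defect")
  # threshold above the defect amplitude: nothing survives
  expect_error(measure_defect_depth(make_profile(x, z), min_amplitude = 60),
               class = "ed_no_defect")
})

test_that("smooth furrows with monotone flanks fall back to the highest occlusal sample", {
  x <- seq(0, 300, by = 1)
  z <- -30 * exp(-(x - 150)^2 / (2 * 30^2))
  m <- measure_defect_depth(make_profile(x, z), min_amplitude = 5)
  expect_equal(m$depth_um, 30, tolerance = 0.01)
  expect_lt(m$shoulder_distance, m$floor_distance)
})

test_that("perikymata depths use the recorded ridge convention", {
  # asymmetric ripple: occlusal ridges higher than cervical ones
  x <- seq(0, 240, by = 1)
  base <- -0.004 * x
  z <- base + 1.5 * (1 + cos(2 * pi * x / 60)) / 2
  p <- make_profile(x, z)
  m_occ <- suppressWarnings(
    measure_perikymata_depths(p, n_target = 3, min_amplitude = 0.2,
                              ridge = "occlusal"))
  expect_true(all(m_occ$ridge_side == "occlusal"))
  expect_true(all(m_occ$ridge_distance < m_occ$groove_distance))
  m_hi <- suppressWarnings(
    measure_perikymata_depths(p, n_target = 3, min_amplitude = 0.2,
                              ridge = "higher"))
  # falling baseline: the occlusal ridge is the higher one, conventions agree
  expect_equal(m_hi$depth_um, m_occ$depth_um)
  # rising baseline: "higher" picks the cervical ridge and exceeds the
  # occlusal-side difference
  z2 <- -base + 1.5 * (1 + cos(2 * pi * x / 60)) / 2
  p2 <- make_profile(x, z2)
  m2_occ <- suppressWarnings(measure_perikymata_depths(
    p2, n_target = 3, min_amplitude = 0.2, ridge = "occlusal"))
  m2_hi <- suppressWarnings(measure_perikymata_depths(
    p2, n_target = 3, min_amplitude = 0.2, ridge = "higher"))
  expect_true(all(m2_hi$depth_um >= m2_occ$depth_um))
  expect_true(any(m2_hi$ridge_side == "cervical"))
})

test_that("uniform synthetic ripple yields uniform perikymata depths", {
  x <- seq(0, 300, by = 0.64)
  z <- -1.5 * (1 - cos(2 * pi * x / 60)) / 2
  m <- suppressWarnings(
    measure_perikymata_depths(make_profile(x, z), n_target = 4,
                              min_amplitude = 0.2))
  expect_equal(nrow(m), 4)
  expect_equal(m$depth_um, rep(1.5, 4), tolerance = 1e-3)

  # flat profile: zero measurements plus a shortfall warning
  flat <- make_profile(x, rep(1, length(x)))
  expect_warning(m0 <- measure_perikymata_depths(flat, n_target = 4),
                 class = "ed_shortfall")
  expect_equal(nrow(m0), 0)
})

test_that("depths are shift-invariant and scale linearly", {
  x <- seq(0, 400, by = 1)
  z <- -25 * exp(-(x - 200)^2 / (2 * 25^2)) + 0.8 * cos(2 * pi * x / 55)
  p0 <- make_profile(x, z)
  m0 <- measure_defect_depth(p0, 5)
  m_shift <- measure_defect_depth(make_profile(x, z + 123.4), 5)
  expect_equal(m_shift$depth_um, m0$depth_um)
  m_scale <- measure_defect_depth(make_profile(x, 2.5 * z), 5 * 2.5)
  expect_equal(m_scale$depth_um, 2.5 * m0$depth_um)
})

test_that("aggregate_feature averages replicates", {
  m <- tibble::tibble(feature_kind = "defect", depth_um = c(29, 30, 31))
  a <- aggregate_feature(m)
  expect_equal(a$mean_depth_um, 30)
  expect_equal(a$range_um, 2)
  expect_equal(a$n, 3)
  one <- aggregate_feature(tibble::tibble(feature_kind = "perikyma",
                                          depth_um = 1.7))
  expect_equal(one$mean_depth_um, 1.7)
  expect_error(aggregate_feature(m[0, ]), class = "ed_aggregation")
  expect_error(aggregate_feature(tibble::tibble(
    feature_kind = c("defect", "perikyma"), depth_um = c(1, 2))),
    class = "ed_aggregation")
})

test_that("short profiles are rejected", {
  expect_error(find_extrema(make_profile(1:5, c(1, 3, 1, 3, 1)), 0),
               class = "ed_bad_input")
})
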