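test_that("spec validation enforces the geometric invariants", {
  expect_error(synthetic_spec(defects = data.frame(center = 50, width = 150,
                                                   depth = 30)),
               class = "ed_spec")  # extends beyond the occlusal edge
  expect_error(synthetic_spec(defects = data.frame(center = 400, width = 30,
                                                   depth = 30)),
               class = "ed_spec")  # narrower than perikymata spacing
  expect_error(synthetic_spec(dropout_rate = 1.5), class = "ed_spec")
  expect_error(synthetic_spec(pixel_pitch = 0), class = "ed_spec")
  expect_s3_class(quick_spec(), "synthetic_spec")
})

test_that("generation is bit-identical under a fixed seed", {
  sp <- quick_spec(noise_sd = 0.05, spike_rate = 0.002, dropout_rate = 0.01)
  s1 <- generate_surface(sp)
  s2 <- generate_surface(sp)
  expect_identical(s1$dem$z, s2$dem$z)
  expect_identical(s1$truth$defects, s2$truth$defects)
  s3 <- generate_surface(quick_spec(noise_sd = 0.05, spike_rate = 0.002,
                                    dropout_rate = 0.01, seed = 2))
  expect_false(identical(s1$dem$z, s3$dem$z))
})

test_that("a flat noise-free furrow has one interior minimum at the stated depth", {
  sp <- quick_spec(perikymata = list(depth_mean = 0.5, depth_sd = 0.001))
  s <- generate_surface(sp)
  p <- extract_profile(s$dem, suggest_transect(s, "defect"))
  ps <- find_extrema(p, min_amplitude = 5)
  expect_equal(nrow(ps$minima), 1)
  m <- measure_defect_depth(p, min_amplitude = 5)
  expect_equal(m$depth_um, s$truth$defects$depth_true, tolerance = 0.02)
  expect_equal(m$depth_um, 30, tolerance = 30 * 0.1)
})

test_that("perikymata-only surfaces recover the configured depth regime", {
  sp <- quick_spec(perikymata = list(depth_mean = 1.57, depth_sd = 0.2),
                   defects = data.frame()[0, ], apex_frac = 0.3,
                   extent = c(120, 900))
  s <- generate_surface(sp)
  trp <- suggest_transect(s, "perikymata")
  m <- suppressWarnings(measure_perikymata_transect(s$dem, trp, n_target = 6))
  expect_gte(nrow(m), 4)
  expect_equal(mean(m$depth_um), 1.57, tolerance = 0.25)
  # per-groove agreement with the analytic in-situ truth
  pkt <- s$truth$perikymata
  for (i in seq_len(nrow(m))) {
    gy <- m$groove_distance[i] + trp$start[2]
    j <- which.min(abs(pkt$y_trough - gy))
    expect_lt(abs(m$depth_um[i] - pkt$depth_true[j]) / pkt$depth_true[j],
              0.05)
  }
})

test_that("curvature at protocol scale changes raw depth by under 5%", {
  for (R in c(5000, 10000)) {
    sp <- quick_spec(crown_radius = R, apex_frac = 0.5,
                     defects = data.frame(center = 400, width = 100,
                                          depth = 30))
    s <- generate_surface(sp)
    expect_lt(abs(s$truth$defects$depth_true - s$truth$defects$depth_feature) /
                s$truth$defects$depth_feature, 0.05)
    m <- suppressWarnings(
      measure_defect_replicates(s$dem, suggest_transect(s, "defect")))
    expect_lt(abs(mean(m$depth_um) - s$truth$defects$depth_feature) /
                s$truth$defects$depth_feature, 0.05)
  }
})

test_that("noise degrades depth accuracy monotonically in expectation", {
  errs <- vapply(c(0, 0.3, 2), function(ns) {
    es <- vapply(1:6, function(k) {
      s <- generate_surface(quick_spec(noise_sd = ns, seed = 100 + k))
      m <- suppressWarnings(
        measure_defect_replicates(s$dem, suggest_transect(s, "defect")))
      abs(mean(m$depth_um) - s$truth$defects$depth_true)
    }, numeric(1))
    mean(es)
  }, numeric(1))
  expect_true(errs[1] <= errs[2] && errs[2] <= errs[3])
})

test_that("spikes and dropouts are applied and cleanable", {
  sp <- quick_spec(noise_sd = 0.02, spike_rate = 0.004,
                   spike_amplitude = 40, dropout_rate = 0.01,
                   defects = data.frame()[0, ])
  s <- generate_surface(sp)
  expect_lt(measured_fraction(s$dem), 1)
  cleaned <- reduce_noise(s$dem, window = 5, k = 3)
  n_spike_before <- sum(abs(s$dem$z - median(s$dem$z, na.rm = TRUE)) > 20,
                        na.rm = TRUE)
  n_spike_after <- sum(abs(cleaned$z - median(cleaned$z, na.rm = TRUE)) > 20,
                       na.rm = TRUE)
  expect_lt(n_spike_after, n_spike_before * 0.2)
})

test_that("cohorts are reproducible, hierarchical and carry usable truth", {
  g <- tibble::tibble(taxon = c("A", "B"), temporal_group = c("x", "y"),
                      n_specimens = c(4, 4), pk_depth_mean = c(1, 2.33),
                      severity_mean = c(17, 17))
  c1 <- generate_cohort(g, seed = 9)
  c2 <- generate_cohort(g, seed = 9)
  expect_identical(c1$defects$depth_um, c2$defects$depth_um)
  expect_identical(c1$perikymata$depth_um, c2$perikymata$depth_um)

  expect_equal(nrow(c1$truth$teeth), 16)
  expect_equal(nrow(c1$defects), 32)
  # every preserved tooth contributes exactly 10 perikymata records
  per_tooth <- table(paste(c1$perikymata$specimen_id,
                           c1$perikymata$tooth_type))
  expect_true(all(per_tooth == 10))
  expect_equal(sum(c1$truth$teeth$pk_preserved) * 10, nrow(c1$perikymata))
  # matched defects share ids across teeth within a specimen
  md <- table(c1$defects$matched_group_id)
  expect_true(all(md == 2))
  expect_error(generate_cohort(g[0, ]), class = "ed_spec")
})

test_that("single specimen with a single defect gives ratio = severity x noise", {
  g <- tibble::tibble(taxon = "A", temporal_group = "x", n_specimens = 1,
                      pk_depth_mean = 1.5, severity_mean = 20)
  co <- generate_cohort(g, teeth_per_specimen = 1, defects_per_tooth = 1,
                        fallback_fraction = 0, seed = 2)
  expect_equal(nrow(co$defects), 1)
  sr <- severity_ratios(co$defects, co$perikymata)
  # the measured ratio deviates from true severity only by the replicate
  # median of the pk noise and the defect's own multiplicative noise
  expect_equal(sr$ratio / co$defects$severity_true, 1, tolerance = 0.5)
})
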