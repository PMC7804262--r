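make_records <- function() {
  pk <- tibble::tibble(
    specimen_id = rep(c("S1", "S2"), each = 10),
    taxon = "H. neanderthalensis",
    tooth_type = "LC",
    feature_kind = "perikyma",
    depth_um = c(seq(1.0, 2.8, length.out = 10),
                 seq(0.8, 2.2, length.out = 10))
  )
  defects <- tibble::tibble(
    specimen_id = c("S1", "S1", "S2", "S3"),
    taxon = "H. neanderthalensis",
    tooth_type = "LC",
    feature_id = c("d1", "d2", "d3", "d4"),
    feature_kind = "defect",
    depth_um = c(26.4, 18, 22, 30),
    pk_preserved = c(TRUE, TRUE, TRUE, FALSE)
  )
  list(pk = pk, defects = defects)
}

test_that("severity ratios use same-tooth medians and the published worked example holds", {
  r <- make_records()
  # engineer S1's perikymata so its median matches a published tooth median
  r$pk$depth_um[1:10] <- 1.57 * c(0.8, 0.9, 0.95, 1, 1, 1, 1, 1.05, 1.2, 1.4)
  sr <- severity_ratios(r$defects, r$pk)
  d1 <- sr[sr$feature_id == "d1", ]
  expect_equal(d1$reference_kind, "same_tooth_median")
  expect_equal(d1$reference_depth_um, 1.57)
  expect_equal(round(d1$ratio, 1), 16.8)

  d2 <- sr[sr$feature_id == "d2", ]
  expect_equal(d2$ratio, 18 / 1.57)
})

test_that("fallback referencing pools the taxon and tooth type and is exact", {
  r <- make_records()
  sr <- severity_ratios(r$defects, r$pk)
  d4 <- sr[sr$feature_id == "d4", ]  # S3 has no pk records
  expect_equal(d4$reference_kind, "species_toothtype_median")
  expect_equal(d4$reference_depth_um, median(r$pk$depth_um))
  expect_equal(d4$ratio, 30 / median(r$pk$depth_um))
  # non-fallback defects never use the pool
  expect_true(all(sr$reference_kind[sr$feature_id != "d4"] ==
                    "same_tooth_median"))

  # no reference anywhere -> classed error naming the defect
  lone <- tibble::tibble(specimen_id = "S9", taxon = "H. sapiens",
                         tooth_type = "UC", feature_id = "dx",
                         feature_kind = "defect", depth_um = 10,
                         pk_preserved = FALSE)
  err <- tryCatch(severity_ratios(lone, r$pk), error = function(e) e)
  expect_s3_class(err, "ed_missing_reference")
  expect_match(conditionMessage(err), "dx")
})

test_that("severity ratios are invariant under unit rescaling", {
  r <- make_records()
  sr <- severity_ratios(r$defects, r$pk)
  r2 <- r
  r2$defects$depth_um <- r2$defects$depth_um * 1000
  r2$pk$depth_um <- r2$pk$depth_um * 1000
  sr2 <- severity_ratios(r2$defects, r2$pk)
  expect_equal(sr2$ratio, sr$ratio)
})

test_that("group summaries equal brute-force order statistics", {
  expect_equal(group_summary(tibble::tibble(
    taxon = "t", tooth_type = "LC", feature_kind = "perikyma",
    depth_um = c(1, 2, 3)))$median, 2)

  withr::local_seed(31)
  rec <- tibble::tibble(
    taxon = sample(c("A", "B"), 200, TRUE),
    tooth_type = sample(c("LC", "LI1", "UI2"), 200, TRUE),
    feature_kind = sample(c("defect", "perikyma"), 200, TRUE),
    depth_um = rlnorm(200, 1, 0.6)
  )
  gs <- group_summary(rec)
  for (i in seq_len(nrow(gs))) {
    sel <- rec$depth_um[rec$taxon == gs$taxon[i] &
                          rec$tooth_type == gs$tooth_type[i] &
                          rec$feature_kind == gs$feature_kind[i]]
    sel <- sort(sel)
    n <- length(sel)
    med <- if (n %% 2 == 1) sel[(n + 1) / 2] else
      (sel[n / 2] + sel[n / 2 + 1]) / 2
    expect_equal(gs$n[i], n)
    expect_equal(gs$median[i], med)
    expect_equal(gs$min[i], sel[1])
    expect_equal(gs$max[i], sel[n])
  }
})

test_that("the shipped median table matches the expected cohort structure", {
  tab <- reference_depth_table()
  expect_equal(nrow(tab), 12)
  expect_equal(sort(unique(tab$tooth_type)),
               c("LC", "LI1", "LI2", "UC", "UI1", "UI2"))
  nean <- tab[tab$taxon == "H. neanderthalensis", ]
  expect_equal(nean$n_pk[nean$tooth_type == "LC"], 10)
  expect_equal(sum(nean$n_defects), 36)
  expect_equal(sum(tab$n_pk), 280)
  expect_equal(sum(tab$n_defects), 71)
})

test_that("correlation runs on log medians and handles degenerate input", {
  tm <- tibble::tibble(pk_median_um = c(1, 2, 4, 8),
                       defect_median_um = c(10, 20, 40, 80))
  ct <- correlate_depths(tm)
  expect_equal(ct$r_squared, 1, tolerance = 1e-12)
  expect_equal(ct$transformation, "natural log")

  expect_error(correlate_depths(tibble::tibble(
    pk_median_um = c(1, 2, -1), defect_median_um = c(1, 2, 3))),
    class = "ed_transform")
  expect_error(correlate_depths(tibble::tibble(
    pk_median_um = c(2, 2, 2), defect_median_um = c(1, 2, 3))),
    class = "ed_degenerate")
  expect_error(correlate_depths(tm[1:2, ]), class = "ed_bad_input")
})

test_that("null correlation has R^2 near 1/(n-1) across replicates", {
  withr::local_seed(13)
  n <- 29
  r2 <- replicate(400, {
    tm <- tibble::tibble(pk_median_um = rlnorm(n, 0, 0.4),
                         defect_median_um = rlnorm(n, 3, 0.4))
    correlate_depths(tm)$r_squared
  })
  expect_lt(abs(mean(r2) - 1 / (n - 1)), 0.012)
})

test_that("mixed model detects nothing when groups are identical and flags bad designs", {
  g <- tibble::tibble(taxon = c("A", "B"), temporal_group = c("x", "y"),
                      n_specimens = c(6, 6), pk_depth_mean = c(1.5, 1.5),
                      severity_mean = c(15, 15))
  co <- generate_cohort(g, seed = 5)
  fm <- fit_group_model(co$defects, response = "log_depth",
                        fixed_factor = "taxon")
  expect_s3_class(fm, "stats_result")
  expect_true(fm$p_value >= 0 && fm$p_value <= 1)
  expect_equal(fm$num_df, 1)

  # all responses equal -> F ~ 0
  rec <- tibble::tibble(specimen_id = rep(c("s1", "s2", "s3", "s4"), each = 4),
                        taxon = rep(c("A", "B"), each = 8),
                        depth_um = 10)
  fm0 <- fit_group_model(rec, response = "log_depth", fixed_factor = "taxon")
  expect_lt(abs(fm0$F), 1e-6)

  one <- tibble::tibble(specimen_id = "s1", taxon = c("A", "B"),
                        depth_um = c(1, 2))
  expect_error(fit_group_model(one, fixed_factor = "taxon"),
               class = "ed_model")
  expect_error(fit_group_model(
    tibble::tibble(specimen_id = c("a", "b"), taxon = "A",
                   depth_um = c(1, 2)), fixed_factor = "taxon"),
    class = "ed_model")
  expect_error(fit_group_model(
    tibble::tibble(specimen_id = c("a", "b"), taxon = c("A", "B"),
                   depth_um = c(-1, 2)), fixed_factor = "taxon"),
    class = "ed_transform")
})

test_that("posthoc contrasts are adjusted, recorded, and warn when redundant", {
  withr::local_seed(8)
  g <- tibble::tibble(taxon = "H", temporal_group = c("MP", "UP", "Neo", "Med"),
                      n_specimens = 5, pk_depth_mean = 2,
                      severity_mean = c(15, 15, 15, 40))
  co <- generate_cohort(g, seed = 17)
  sr <- severity_ratios(co$defects, co$perikymata)
  rec <- dplyr::left_join(sr,
                          dplyr::distinct(co$defects[, c("feature_id",
                                                         "temporal_group")]),
                          by = "feature_id")
  fm <- fit_group_model(rec, response = "log_ratio",
                        fixed_factor = "temporal_group")
  pc <- posthoc_contrasts(fm)
  expect_equal(pc$adjust_method, "tukey")
  expect_equal(nrow(pc$contrasts), 6)
  # adjusted p never below the unadjusted Holm analogue of itself:
  ph <- posthoc_contrasts(fm, adjust = "holm")
  raw_p <- 2 * stats::pt(-abs(pc$contrasts$t), pc$contrasts$df)
  expect_true(all(pc$contrasts$p_value >= raw_p - 1e-12))
  expect_true(all(ph$contrasts$p_value >= raw_p - 1e-12))

  g2 <- tibble::tibble(taxon = c("A", "B"), temporal_group = c("x", "y"),
                       n_specimens = 4, pk_depth_mean = 1.5,
                       severity_mean = 15)
  co2 <- generate_cohort(g2, seed = 3)
  fm2 <- fit_group_model(co2$defects, response = "log_depth",
                         fixed_factor = "taxon")
  expect_warning(posthoc_contrasts(fm2), class = "ed_redundant_contrast")
})

test_that("replicability report uses the symmetric denominator", {
  a <- tibble::tibble(feature_id = c("f1", "f2"), feature_kind = "defect",
                      depth_um = c(30, 50))
  b <- tibble::tibble(feature_id = c("f1", "f2"), feature_kind = "defect",
                      depth_um = c(30.69, 50))
  rep <- replicability_compare(a, b)
  f1 <- rep$per_feature[rep$per_feature$feature_id == "f1", ]
  expect_equal(round(f1$percent_difference, 1), 2.3)
  expect_equal(f1$absolute_difference, 0.69)
  f2 <- rep$per_feature[rep$per_feature$feature_id == "f2", ]
  expect_equal(f2$percent_difference, 0)

  withr::local_seed(4)
  a5 <- tibble::tibble(feature_id = paste0("f", 1:5), feature_kind = "defect",
                       depth_um = runif(5, 20, 60))
  b5 <- a5; b5$depth_um <- b5$depth_um * runif(5, 0.96, 1.04)
  r5 <- replicability_compare(a5, b5)
  expect_equal(r5$summary$mean_percent,
               mean(200 * abs(a5$depth_um - b5$depth_um) /
                      (a5$depth_um + b5$depth_um)))
  expect_error(replicability_compare(a, b[1, ]), class = "ed_pairing")
})
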