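#' LEH severity ratios with tooth-level and species-level references
#'
#' Scales each defect depth by a perikymata reference depth so that stress
#' severity can be compared across teeth and taxa with different enamel
#' growth rates. The reference is the median perikymata depth of the *same
#' tooth* (same specimen and tooth type) when that tooth's perikymata are
#' well-enough preserved to measure; otherwise the median over all perikymata
#' of the same taxon and tooth type (the fallback rule). The reference kind
#' used is recorded per defect.
#'
#' @param defects Tibble of defect records: `specimen_id`, `taxon`,
#'   `tooth_type`, `feature_id`, `depth_um`, `pk_preserved` (logical).
#' @param perikymata Tibble of perikymata records: `specimen_id`, `taxon`,
#'   `tooth_type`, `depth_um`.
#' @return A tibble with one row per defect: identifiers, `depth_um`,
#'   `reference_kind` (`"same_tooth_median"` or
#'   `"species_toothtype_median"`), `reference_depth_um` and `ratio`.
#' @export
severity_ratios <- function(defects, perikymata) {
  defects <- tibble::as_tibble(defects)
  perikymata <- tibble::as_tibble(perikymata)
  need_d <- c("specimen_id", "taxon", "tooth_type", "feature_id",
              "depth_um", "pk_preserved")
  need_p <- c("specimen_id", "taxon", "tooth_type", "depth_um")
  if (!all(need_d %in% names(defects))) {
    ed_stop(paste("defect records need columns:",
                  paste(setdiff(need_d, names(defects)), collapse = ", ")),
            "ed_bad_input")
  }
  if (!all(need_p %in% names(perikymata))) {
    ed_stop(paste("perikymata records need columns:",
                  paste(setdiff(need_p, names(perikymata)), collapse = ", ")),
            "ed_bad_input")
  }
  out <- vector("list", nrow(defects))
  for (i in seq_len(nrow(defects))) {
    d <- defects[i, ]
    same <- perikymata$depth_um[
      perikymata$specimen_id == d$specimen_id &
        perikymata$tooth_type == d$tooth_type
    ]
    if (isTRUE(d$pk_preserved) && length(same) > 0) {
      ref <- median(same); kind <- "same_tooth_median"
    } else {
      pool <- perikymata$depth_um[
        perikymata$taxon == d$taxon & perikymata$tooth_type == d$tooth_type
      ]
      if (length(pool) == 0) {
        ed_stop(sprintf(
          "no perikymata reference at tooth or species level for defect '%s'",
          d$feature_id), "ed_missing_reference")
      }
      ref <- median(pool); kind <- "species_toothtype_median"
    }
    out[[i]] <- tibble::tibble(
      feature_id = d$feature_id, specimen_id = d$specimen_id,
      taxon = d$taxon, tooth_type = d$tooth_type,
      depth_um = d$depth_um,
      reference_kind = kind, reference_depth_um = ref,
      ratio = d$depth_um / ref
    )
  }
  dplyr::bind_rows(out)
}

#' Group summary of depths (taxon x tooth type x feature kind)
#'
#' Per-group count, median and range, the structure of a taxon-by-tooth-type
#' depth table. Medians of even-sized groups are midpoints of the two central
#' order statistics.
#'
#' @param records Tibble with `taxon`, `tooth_type`, `feature_kind`,
#'   `depth_um` (any extra grouping columns in `by` are honoured).
#' @param by Grouping columns; default
#'   `c("taxon", "tooth_type", "feature_kind")`.
#' @param value Column to summarise; default `"depth_um"`.
#' @return A tibble: grouping columns, `n`, `median`, `min`, `max`.
#' @export
group_summary <- function(records,
                          by = c("taxon", "tooth_type", "feature_kind"),
                          value = "depth_um") {
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0) ed_stop("records must be nonempty", "ed_bad_input")
  if (!all(c(by, value) %in% names(records))) {
    ed_stop("missing grouping or value columns", "ed_bad_input")
  }
  dplyr::summarise(
    dplyr::group_by(records, dplyr::across(dplyr::all_of(by))),
    n = dplyr::n(),
    median = median(.data[[value]]),
    min = min(.data[[value]]),
    max = max(.data[[value]]),
    .groups = "drop"
  )
}

#' Published median depth table for the worked examples
#'
#' Taxon-by-tooth-type medians and ranges of perikymata depth, defect depth
#' and severity ratio for Neanderthal and *H. sapiens* anterior teeth,
#' shipped as a plain CSV. Used for worked-example arithmetic (for the lower
#' teeth the printed severity-ratio median equals the ratio of the printed
#' defect and perikymata medians) and as realistic parameter regimes for the
#' synthetic generator.
#'
#' @return A tibble with columns `taxon`, `tooth_type`, `n_pk`, `pk_median`,
#'   `pk_min`, `pk_max`, `n_defects`, `defect_median`, `defect_min`,
#'   `defect_max`, `severity_median`, `severity_min`, `severity_max`.
#' @export
reference_depth_table <- function() {
  readr::read_csv(
    system.file("extdata", "anterior_tooth_depth_medians.csv",
                package = "enameldepth"),
    col_types = readr::cols(
      taxon = "c", tooth_type = "c",
      .default = readr::col_double()
    )
  )
}

#' Correlate perikymata and defect depths across teeth
#'
#' Pearson correlation of natural-log-transformed per-tooth median depths
#' (both depth distributions are right-skewed, hence the log).
#'
#' @param tooth_medians Tibble with `pk_median_um` and `defect_median_um`,
#'   one row per tooth with both medians available (`>= 3` rows).
#' @return A `stats_result` list: `r`, `r_squared`, `t`, `df`, `p_value`,
#'   the transformation applied, and the method description.
#' @export
correlate_depths <- function(tooth_medians) {
  tm <- tibble::as_tibble(tooth_medians)
  if (!all(c("pk_median_um", "defect_median_um") %in% names(tm))) {
    ed_stop("need pk_median_um and defect_median_um columns", "ed_bad_input")
  }
  tm <- tm[complete.cases(tm[, c("pk_median_um", "defect_median_um")]), ]
  if (nrow(tm) < 3) ed_stop("need >= 3 teeth with both medians", "ed_bad_input")
  if (any(tm$pk_median_um <= 0) || any(tm$defect_median_um <= 0)) {
    ed_stop("depths must be positive for log transformation", "ed_transform")
  }
  lx <- log(tm$pk_median_um); ly <- log(tm$defect_median_um)
  if (sd(lx) == 0 || sd(ly) == 0) {
    ed_stop("zero variance in log medians: correlation undefined",
            "ed_degenerate")
  }
  ct <- cor.test(lx, ly, method = "pearson")
  structure(
    list(
      analysis_kind = "correlation",
      method = "Pearson on natural-log per-tooth medians",
      n = nrow(tm),
      r = unname(ct$estimate),
      r_squared = unname(ct$estimate)^2,
      t = unname(ct$statistic),
      df = unname(ct$parameter),
      p_value = ct$p.value,
      transformation = "natural log"
    ),
    class = "stats_result"
  )
}

#' Linear mixed model for group differences in depth or severity
#'
#' Fits `response ~ fixed_factor + (1 | specimen_id)`: the specimen-level
#' random intercept absorbs the dependence created by measuring multiple
#' features (including matched defects) per individual. Depth responses are
#' natural-log-transformed; severity ratios are log-transformed by default
#' (log preserves ratio symmetry) but can be analysed untransformed. The
#' fixed effect is tested with a Satterthwaite F test.
#'
#' @param records Tibble with the response column, the fixed-factor column
#'   and `specimen_id`.
#' @param response `"log_depth"` (log of `depth_um`), `"log_ratio"` (log of
#'   `ratio`) or `"ratio"` (untransformed).
#' @param fixed_factor Name of the grouping column (`>= 2` levels).
#' @return A `stats_result`: fixed-effect estimates with standard errors and
#'   Wald 95% confidence intervals, `F`, numerator/denominator dfs,
#'   `p_value`, the fitted model (for posthoc contrasts) and a formula
#'   description.
#' @export
fit_group_model <- function(records,
                            response = c("log_depth", "log_ratio", "ratio"),
                            fixed_factor = "taxon") {
  response <- match.arg(response)
  records <- tibble::as_tibble(records)
  src <- switch(response, log_depth = "depth_um", log_ratio = "ratio",
                ratio = "ratio")
  if (!all(c(src, fixed_factor, "specimen_id") %in% names(records))) {
    ed_stop(sprintf("records need columns: %s, %s, specimen_id",
                    src, fixed_factor), "ed_bad_input")
  }
  y <- records[[src]]
  if (response != "ratio") {
    if (any(y <= 0)) ed_stop("nonpositive response: cannot log", "ed_transform")
    y <- log(y)
  }
  g <- factor(records[[fixed_factor]])
  if (nlevels(g) < 2) {
    ed_stop("fixed factor needs >= 2 levels", "ed_model")
  }
  spec <- factor(records$specimen_id)
  if (nlevels(spec) < 2) {
    ed_stop(paste0("only one specimen: random intercept inestimable; ",
                   "fit a fixed-effects model instead"), "ed_model")
  }
  dat <- data.frame(.y = y, .g = g, .spec = spec)
  if (sd(y) < 1e-12) {
    # degenerate response: no variance anywhere, the group effect is exactly 0
    return(structure(
      list(analysis_kind = "mixed_model",
           formula = sprintf("%s ~ %s + (1 | specimen_id)", response,
                             fixed_factor),
           response = response, fixed_factor = fixed_factor,
           estimates = tibble::tibble(term = character(), estimate = numeric(),
                                      se = numeric(), df = numeric(),
                                      ci_lower = numeric(),
                                      ci_upper = numeric()),
           F = 0, num_df = nlevels(g) - 1, den_df = NA_real_, p_value = 1,
           transformation = if (response == "ratio") "none" else "natural log",
           n_obs = nrow(dat), n_specimens = nlevels(spec), model = NULL),
      class = "stats_result"
    ))
  }
  m <- suppressMessages(suppressWarnings(
    lmerTest::lmer(.y ~ .g + (1 | .spec), data = dat,
                   control = lme4::lmerControl(calc.derivs = FALSE,
                                               check.conv.singular = "ignore"))
  ))
  a <- suppressMessages(suppressWarnings(anova(m)))
  cf <- summary(m)$coefficients
  tq <- stats::qt(0.975, pmax(cf[, "df"], 1))
  est <- tibble::tibble(
    term = rownames(cf),
    estimate = cf[, "Estimate"],
    se = cf[, "Std. Error"],
    df = cf[, "df"],
    ci_lower = cf[, "Estimate"] - tq * cf[, "Std. Error"],
    ci_upper = cf[, "Estimate"] + tq * cf[, "Std. Error"]
  )
  structure(
    list(
      analysis_kind = "mixed_model",
      formula = sprintf("%s ~ %s + (1 | specimen_id)",
                        switch(response, log_depth = "log(depth)",
                               log_ratio = "log(ratio)", ratio = "ratio"),
                        fixed_factor),
      response = response,
      fixed_factor = fixed_factor,
      estimates = est,
      F = a$`F value`[1],
      num_df = a$NumDF[1],
      den_df = a$DenDF[1],
      p_value = a$`Pr(>F)`[1],
      transformation = if (response == "ratio") "none" else "natural log",
      n_obs = nrow(dat),
      n_specimens = nlevels(spec),
      model = m
    ),
    class = "stats_result"
  )
}

#' All-pairwise posthoc contrasts for a fitted group model
#'
#' Estimated marginal means with Tukey-adjusted (default) or Holm-adjusted
#' pairwise comparisons; the adjustment method is recorded in the result.
#'
#' @param result A `stats_result` from [fit_group_model()] whose fixed
#'   factor has `>= 3` levels (with 2 levels the contrast equals the main
#'   test and a redundancy warning is raised).
#' @param adjust `"tukey"` or `"holm"`.
#' @return A `stats_result` with a `contrasts` tibble (`contrast`,
#'   `estimate`, `se`, `df`, `t`, `p_value`) and `adjust_method`.
#' @export
posthoc_contrasts <- function(result, adjust = c("tukey", "holm")) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(result, "stats_result"))
  if (is.null(result$model)) {
    ed_stop("result carries no fitted model", "ed_bad_input")
  }
  nlev <- nlevels(result$model@frame$.g)
  if (nlev < 3) {
    ed_warn("factor has 2 levels: pairwise contrast equals the main test",
            "ed_redundant_contrast")
  }
  em <- suppressMessages(emmeans::emmeans(result$model, ".g",
                                          lmer.df = "satterthwaite"))
  pr <- as.data.frame(summary(emmeans::contrast(em, method = "pairwise",
                                                adjust = adjust)))
  structure(
    list(
      analysis_kind = "posthoc",
      adjust_method = adjust,
      fixed_factor = result$fixed_factor,
      contrasts = tibble::tibble(
        contrast = as.character(pr$contrast),
        estimate = pr$estimate,
        se = pr$SE,
        df = pr$df,
        t = pr$t.ratio,
        p_value = pr$p.value
      )
    ),
    class = "stats_result"
  )
}

#' Compare matched depth measurements between two sessions
#'
#' Paired replicability report for the same features measured on two
#' instruments or in two sessions: per-feature absolute differences (um) and
#' symmetric percent differences (`100 * |a - b| / mean(a, b)`), summarised
#' by feature kind.
#'
#' @param session_a,session_b Tibbles with `feature_id`, `feature_kind`,
#'   `depth_um`; feature ids must match across sessions.
#' @return A `replicability_report` with `per_feature` and `summary` tibbles.
#' @export
replicability_compare <- function(session_a, session_b) {
  a <- tibble::as_tibble(session_a); b <- tibble::as_tibble(session_b)
  need <- c("feature_id", "feature_kind", "depth_um")
  if (!all(need %in% names(a)) || !all(need %in% names(b))) {
    ed_stop("sessions need feature_id, feature_kind, depth_um", "ed_bad_input")
  }
  if (!setequal(a$feature_id, b$feature_id)) {
    ed_stop("unmatched feature_ids between sessions", "ed_pairing")
  }
  m <- dplyr::inner_join(
    dplyr::select(a, "feature_id", "feature_kind", depth_a = "depth_um"),
    dplyr::select(b, "feature_id", depth_b = "depth_um"),
    by = "feature_id"
  )
  m$absolute_difference <- abs(m$depth_a - m$depth_b)
  m$percent_difference <- 100 * m$absolute_difference /
    ((m$depth_a + m$depth_b) / 2)
  s <- dplyr::summarise(
    dplyr::group_by(m, .data$feature_kind),
    n = dplyr::n(),
    mean_percent = mean(.data$percent_difference),
    min_percent = min(.data$percent_difference),
    max_percent = max(.data$percent_difference),
    mean_abs_um = mean(.data$absolute_difference),
    min_abs_um = min(.data$absolute_difference),
    max_abs_um = max(.data$absolute_difference),
    .groups = "drop"
  )
  structure(list(per_feature = m, summary = s),
            class = "replicability_report")
}

#' @export
print.replicability_report <- function(x, ...) {
  cat("<replicability_report>\n")
  print(x$summary)
  invisible(x)
}

#' @export
print.stats_result <- function(x, ...) {
  cat(sprintf("<stats_result: %s>\n", x$analysis_kind))
  if (x$analysis_kind == "correlation") {
    cat(sprintf("  r = %.3f, R^2 = %.3f, t(%d) = %.2f, p = %.4g (n = %d)\n",
                x$r, x$r_squared, x$df, x$t, x$p_value, x$n))
  } else if (x$analysis_kind == "mixed_model") {
    cat(sprintf("  %s\n  F(%d, %.1f) = %.2f, p = %.4g\n",
                x$formula, x$num_df, x$den_df, x$F, x$p_value))
  } else if (x$analysis_kind == "posthoc") {
    cat(sprintf("  %s-adjusted pairwise contrasts on %s\n",
                x$adjust_method, x$fixed_factor))
    print(x$contrasts)
  }
  invisible(x)
}
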