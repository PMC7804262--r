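#' Specify a synthetic tooth-crown surface
#'
#' Parameters of the simulated outer-enamel topography used for validation:
#' a cylindrically curved crown (curvature along the cuspo-cervical y axis,
#' apex toward the occlusal end), a quasi-periodic perikymata ripple whose
#' spacing tightens toward the cervix, Gaussian furrow-form (or smoothed
#' box plane-form) defects, plus instrument effects: Gaussian height noise,
#' spike outliers, and unmeasured dropouts.
#'
#' Defaults emulate a single defect-centred scan field of an anterior tooth:
#' 500 x 1200 um field of view at 0.64 um/pixel, crown radius 5 mm, one
#' 30-um-deep furrow defect mid-field, perikymata of mean depth 2 um and
#' mean spacing 60 um, and a 0.5% dropout rate (a 99.5% measured-point
#' scan).
#'
#' @param extent (width, length) of the field in um; y (length) runs
#'   occlusal (0) to cervical.
#' @param pixel_pitch Grid pitch, um/pixel.
#' @param crown_radius Cylindrical crown radius of curvature in um;
#'   `Inf` for a flat field.
#' @param apex_frac Position of the crown apex along y as a fraction of the
#'   field length.
#' @param perikymata List: `mean_spacing` (um), `spacing_gradient`
#'   (fractional spacing decrease from occlusal to cervical end),
#'   `depth_mean`, `depth_sd` (um), `asymmetry` in (-1, 1).
#' @param defects Data frame: `center` (um along y), `width` (um), `depth`
#'   (um), `shape` (`"gaussian_furrow"` or `"box_plane"`). May have 0 rows.
#' @param noise_sd Gaussian height-noise sd, um.
#' @param spike_rate,spike_amplitude Proportion of cells hit by spikes and
#'   their height, um.
#' @param dropout_rate Proportion of unmeasured cells.
#' @param seed Integer seed; same spec + seed reproduces the surface
#'   bit-identically.
#' @return A validated `synthetic_spec` list.
#' @export
synthetic_spec <- function(extent = c(500, 1200),
                           pixel_pitch = 0.64,
                           crown_radius = 5000,
                           apex_frac = 0.15,
                           perikymata = list(),
                           defects = NULL,
                           noise_sd = 0.05,
                           spike_rate = 0.001,
                           spike_amplitude = 25,
                           dropout_rate = 0.005,
                           seed = 1L) {
  pk <- modifyList(
    list(mean_spacing = 60, spacing_gradient = 0.15,
         depth_mean = 2, depth_sd = 0.5, asymmetry = 0.3),
    perikymata
  )
  if (is.null(defects)) {
    defects <- tibble::tibble(center = extent[2] / 2, width = 150,
                              depth = 30, shape = "gaussian_furrow")
  }
  defects <- tibble::as_tibble(defects)
  if (nrow(defects) > 0 && !"shape" %in% names(defects)) {
    defects$shape <- "gaussian_furrow"
  }
  if (any(extent <= 0) || pixel_pitch <= 0 || crown_radius <= 0) {
    ed_stop("extent, pixel_pitch and crown_radius must be > 0", "ed_spec")
  }
  for (r in c(spike_rate, dropout_rate)) {
    if (r < 0 || r > 1) ed_stop("rates must be in [0, 1]", "ed_spec")
  }
  if (pk$mean_spacing <= 0 || pk$depth_mean <= 0) {
    ed_stop("perikymata spacing and depth must be > 0", "ed_spec")
  }
  if (abs(pk$asymmetry) >= 1) ed_stop("|asymmetry| must be < 1", "ed_spec")
  if (nrow(defects) > 0) {
    if (any(defects$depth <= 0) || any(defects$width <= 0)) {
      ed_stop("defect depth and width must be > 0", "ed_spec")
    }
    if (any(defects$width <= pk$mean_spacing)) {
      ed_stop("defect widths must exceed the perikymata mean spacing",
              "ed_spec")
    }
    if (any(defects$center - defects$width < 0 |
            defects$center + defects$width > extent[2])) {
      ed_stop("defect (center +/- width) extends beyond the surface",
              "ed_spec")
    }
    if (!all(defects$shape %in% c("gaussian_furrow", "box_plane"))) {
      ed_stop("defect shape must be gaussian_furrow or box_plane", "ed_spec")
    }
  }
  if (apex_frac < 0 || apex_frac > 1) ed_stop("apex_frac in [0, 1]", "ed_spec")
  structure(
    list(extent = extent, pixel_pitch = pixel_pitch,
         crown_radius = crown_radius, apex_frac = apex_frac,
         perikymata = pk, defects = defects, noise_sd = noise_sd,
         spike_rate = spike_rate, spike_amplitude = spike_amplitude,
         dropout_rate = dropout_rate, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

# deterministic perikyma layout for a spec: ridge boundaries along y and one
# groove depth per interval (drawn under the spec seed, independent of the
# cell-level noise stream)
pk_layout <- function(spec) {
  L <- spec$extent[2]
  pk <- spec$perikymata
  spacing_at <- function(y) {
    pmax(pk$mean_spacing * (1 - pk$spacing_gradient * (y / L - 0.5)),
         pk$mean_spacing * 0.2)
  }
  b <- 0
  repeat {
    nxt <- b[length(b)] + spacing_at(b[length(b)])
    b <- c(b, nxt)
    if (nxt > L) break
  }
  depths <- pmax(rnorm(length(b) - 1, pk$depth_mean, pk$depth_sd),
                 0.2 * pk$depth_mean)
  list(boundaries = b, depths = depths)
}

# continuous feature component (perikymata ripple + defects), vectorised in y
feature_fun <- function(spec, layout) {
  a <- spec$perikymata$asymmetry
  b <- layout$boundaries
  dpt <- layout$depths
  defects <- spec$defects
  function(y) {
    k <- findInterval(y, b, rightmost.closed = TRUE)
    k <- pmin(pmax(k, 1L), length(dpt))
    u <- (y - b[k]) / (b[k + 1L] - b[k])
    u <- pmin(pmax(u, 0), 1)
    g <- u + a * u * (1 - u)  # monotone warp: skews the groove occlusally
    z <- -dpt[k] * (1 - cos(2 * pi * g)) / 2
    if (nrow(defects) > 0) {
      for (j in seq_len(nrow(defects))) {
        c_j <- defects$center[j]; w <- defects$width[j]; d <- defects$depth[j]
        if (defects$shape[j] == "gaussian_furrow") {
          z <- z - d * exp(-(y - c_j)^2 / (2 * (w / 4)^2))
        } else {
          tau <- w / 20
          z <- z - d * (stats::plogis((y - (c_j - w / 2)) / tau) -
                          stats::plogis((y - (c_j + w / 2)) / tau))
        }
      }
    }
    z
  }
}

# crown form component (cylindrical cap along y), 0 at the apex
form_fun <- function(spec) {
  R <- spec$crown_radius
  y_apex <- spec$apex_frac * spec$extent[2]
  function(y) {
    if (is.infinite(R)) return(rep(0, length(y)))
    sqrt(pmax(R^2 - (y - y_apex)^2, 0)) - R
  }
}

#' Generate a synthetic crown surface with ground truth
#'
#' Builds the elevation field `form + perikymata ripple + defect furrows`,
#' adds Gaussian noise, spike outliers and dropouts last, and returns the
#' surface as both a [point_cloud()] and a [dem()] together with full ground
#' truth. True depths are evaluated analytically on a fine 1-D grid of the
#' noise-free surface using the same shoulder conventions as the measurement
#' stage ([measure_defect_depth()], [measure_perikymata_depths()]):
#' `depth_true` is in-situ (feature + crown form, what a raw-DEM measurement
#' targets) and `depth_feature` is the feature component alone (what the
#' form-free depth would be). Regenerating with the same spec and seed gives
#' bit-identical output.
#'
#' @param spec A [synthetic_spec()].
#' @return A list: `cloud`, `dem`, `truth` (tibbles `defects` and
#'   `perikymata`, the `pk_region` suggested for perikymata transects, the
#'   component functions, and the spec).
#' @export
generate_surface <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(spec$seed)

  layout <- pk_layout(spec)
  ff <- feature_fun(spec, layout)
  fm <- form_fun(spec)
  total <- function(y) ff(y) + fm(y)

  xs <- seq(0, spec$extent[1], by = spec$pixel_pitch)
  ys <- seq(0, spec$extent[2], by = spec$pixel_pitch)
  zy <- total(ys)
  z <- matrix(rep(zy, times = length(xs)), nrow = length(ys))
  n <- length(z)
  if (spec$noise_sd > 0) z <- z + rnorm(n, 0, spec$noise_sd)
  if (spec$spike_rate > 0) {
    hit <- which(runif(n) < spec$spike_rate)
    z[hit] <- z[hit] + sample(c(-1, 1), length(hit), replace = TRUE) *
      spec$spike_amplitude
  }
  if (spec$dropout_rate > 0) {
    z[runif(n) < spec$dropout_rate] <- NA_real_
  }

  d <- dem(z, pixel_pitch = spec$pixel_pitch, origin = c(0, 0),
           occlusal_axis = "row-",
           provenance = c(sprintf("synthetic(seed=%d)", spec$seed)))
  cloud <- dem_to_cloud(d, source_id = sprintf("synthetic(seed=%d)", spec$seed))
  cloud$z_step <- 1

  # ground truth on a fine grid (quarter-pixel), noise-free
  yf <- seq(0, spec$extent[2], by = spec$pixel_pitch / 4)
  zt <- total(yf)
  zf <- ff(yf)
  def_rows <- list()
  if (nrow(spec$defects) > 0) {
    for (j in seq_len(nrow(spec$defects))) {
      c_j <- spec$defects$center[j]; w <- spec$defects$width[j]
      win <- yf >= c_j - w & yf <= c_j + w
      truth_depth <- function(v) {
        i_fl <- which(win)[which.min(v[win])]
        occl <- v[seq_len(i_fl)][yf[seq_len(i_fl)] >= c_j - w]
        list(floor_y = yf[i_fl],
             depth = max(occl) - v[i_fl])
      }
      t_tot <- truth_depth(zt)
      t_feat <- truth_depth(zf)
      def_rows[[j]] <- tibble::tibble(
        defect_id = sprintf("D%02d", j),
        center = c_j, width = w,
        depth_nominal = spec$defects$depth[j],
        shape = spec$defects$shape[j],
        depth_true = t_tot$depth, floor_y = t_tot$floor_y,
        depth_feature = t_feat$depth
      )
    }
  }
  defects_truth <- if (length(def_rows)) dplyr::bind_rows(def_rows) else
    tibble::tibble(defect_id = character(), center = numeric(),
                   width = numeric(), depth_nominal = numeric(),
                   shape = character(), depth_true = numeric(),
                   floor_y = numeric(), depth_feature = numeric())

  b <- layout$boundaries
  in_defect <- function(y) {
    if (nrow(spec$defects) == 0) return(rep(FALSE, length(y)))
    out <- rep(FALSE, length(y))
    for (j in seq_len(nrow(spec$defects))) {
      out <- out | abs(y - spec$defects$center[j]) <= spec$defects$width[j]
    }
    out
  }
  pk_rows <- list()
  for (k in seq_len(length(b) - 2)[-1]) {  # interior intervals only
    lo <- b[k]; hi <- b[k + 1]
    if (hi > spec$extent[2]) next
    s_half <- (hi - lo) / 4
    seg <- yf >= lo & yf <= hi
    i_tr <- which(seg)[which.min(zt[seg])]
    ridge_val <- function(center) {
      m <- yf >= center - s_half & yf <= center + s_half
      max(zt[m])
    }
    r_occ <- ridge_val(lo); r_cer <- ridge_val(hi)
    pk_rows[[length(pk_rows) + 1L]] <- tibble::tibble(
      interval = k,
      y_occlusal_ridge = lo, y_cervical_ridge = hi,
      y_trough = yf[i_tr],
      depth_nominal = layout$depths[k],
      depth_true = max(r_occ, r_cer) - zt[i_tr],
      depth_true_occlusal = r_occ - zt[i_tr],
      in_defect = any(in_defect(c(lo, yf[i_tr], hi)))
    )
  }
  pk_truth <- dplyr::bind_rows(pk_rows)

  # suggested perikymata transect region: defect-free intervals nearest the
  # crown apex (the flattest part of the field)
  y_apex <- spec$apex_frac * spec$extent[2]
  free <- pk_truth[!pk_truth$in_defect, ]
  pk_region <- NULL
  if (nrow(free) >= 2) {
    iv <- sort(free$interval)
    runs <- split(iv, cumsum(c(1, diff(iv) != 1)))
    mid_of <- function(run) {
      sel <- pk_truth[pk_truth$interval %in% run, ]
      mean(c(min(sel$y_occlusal_ridge), max(sel$y_cervical_ridge)))
    }
    # prefer the run nearest the crown apex (the flattest part of the
    # field); ignore 1-interval runs when longer ones exist
    keep <- lengths(runs) >= min(2, max(lengths(runs)))
    runs <- runs[keep]
    run <- runs[[which.min(vapply(runs, function(r) abs(mid_of(r) - y_apex),
                                  numeric(1)))]]
    if (length(run) > 6) {
      # trim to the 6 intervals nearest the apex, keeping contiguity
      dists <- vapply(run, function(k) {
        sel <- pk_truth[pk_truth$interval == k, ]
        abs((sel$y_occlusal_ridge + sel$y_cervical_ridge) / 2 - y_apex)
      }, numeric(1))
      o <- order(dists)[1:6]
      run <- sort(run[o])
      run <- seq(min(run), max(run))
    }
    sel <- pk_truth[pk_truth$interval %in% run, ]
    pk_region <- c(min(sel$y_occlusal_ridge), max(sel$y_cervical_ridge))
  }

  list(
    cloud = cloud,
    dem = d,
    truth = list(
      defects = defects_truth,
      perikymata = pk_truth,
      pk_region = pk_region,
      form_fun = fm,
      feature_fun = ff,
      layout = layout,
      spec = spec
    )
  )
}

#' Suggest measurement transects from ground truth
#'
#' Builds transects the way an analyst would draw them: for a defect, along
#' the cuspo-cervical midline across the defect window (occlusal shoulder to
#' cervical shoulder); for perikymata, across the suggested defect-free
#' region nearest the crown apex.
#'
#' @param surface Result of [generate_surface()].
#' @param what `"defect"` or `"perikymata"`.
#' @param defect_id Which defect (default: first).
#' @param n_intervals For perikymata: number of defect-free growth increments
#'   nearest the apex to span (default `NULL`: the stored suggested region,
#'   up to six increments). Fewer increments keep the transect on the
#'   flattest part of a strongly curved crown.
#' @return A [transect()] with the occlusal end at its start.
#' @export
suggest_transect <- function(surface, what = c("defect", "perikymata"),
                             defect_id = NULL, n_intervals = NULL) {
  what <- match.arg(what)
  tr <- surface$truth
  x_mid <- tr$spec$extent[1] / 2
  if (what == "defect") {
    dd <- tr$defects
    if (nrow(dd) == 0) ed_stop("surface has no defects", "ed_bad_input")
    row <- if (is.null(defect_id)) dd[1, ] else dd[dd$defect_id == defect_id, ]
    if (nrow(row) == 0) ed_stop("unknown defect_id", "ed_bad_input")
    transect(c(x_mid, max(0, row$center - row$width)),
             c(x_mid, min(tr$spec$extent[2], row$center + row$width)),
             occlusal_end = "start")
  } else {
    if (!is.null(n_intervals)) {
      y_apex <- tr$spec$apex_frac * tr$spec$extent[2]
      free <- tr$perikymata[!tr$perikymata$in_defect, ]
      if (nrow(free) < 1) {
        ed_stop("no defect-free perikymata available", "ed_bad_input")
      }
      # work within one contiguous defect-free run (never span a defect):
      # take the run nearest the apex, then its n increments nearest the apex
      iv <- sort(free$interval)
      runs <- split(iv, cumsum(c(1, diff(iv) != 1)))
      run_dist <- vapply(runs, function(r) {
        min(abs(free$y_trough[free$interval %in% r] - y_apex))
      }, numeric(1))
      run <- runs[[which.min(run_dist)]]
      sel <- free[free$interval %in% run, ]
      sel <- sel[order(abs(sel$y_trough - y_apex)), ]
      sel <- sel[seq_len(min(n_intervals, nrow(sel))), ]
      return(transect(c(x_mid, min(sel$y_occlusal_ridge)),
                      c(x_mid, max(sel$y_cervical_ridge)),
                      occlusal_end = "start"))
    }
    if (is.null(tr$pk_region)) {
      ed_stop("no defect-free perikymata region available", "ed_bad_input")
    }
    transect(c(x_mid, tr$pk_region[1]), c(x_mid, tr$pk_region[2]),
             occlusal_end = "start")
  }
}

#' Generate a hierarchical measurement cohort with known truth
#'
#' Simulates the record structure of a multi-site comparative study:
#' specimens nested in groups, teeth nested in specimens, ten perikymata
#' records per well-preserved tooth and replicate-mean defect depths built
#' multiplicatively as `severity x tooth perikymata median x noise`, with
#' lognormal specimen, tooth and residual effects. A stated fraction of
#' teeth is flagged `pk_preserved = FALSE` (their perikymata records are
#' withheld, so severity referencing must fall back to the taxon +
#' tooth-type pool); each stratum keeps at least one preserved tooth so a
#' fallback pool always exists. Defects sharing an index across the teeth of
#' one specimen share a `matched_group_id`, emulating matched defects from
#' one systemic stress episode.
#'
#' @param groups Tibble with one row per group: `taxon`, `temporal_group`,
#'   `n_specimens`, `pk_depth_mean` (um), `severity_mean`
#'   (defect/perikymata depth ratio).
#' @param teeth_per_specimen,defects_per_tooth,pk_per_tooth Counts.
#' @param tooth_types Tooth types cycled across each specimen's teeth.
#' @param specimen_sd,tooth_sd,pk_rep_sd,severity_sd,defect_noise_sd
#'   Lognormal scale (sd of log) of the corresponding effects.
#' @param fallback_fraction Probability a tooth's perikymata are too poorly
#'   preserved to measure (default 12/71, the emulated regime).
#' @param seed Integer seed.
#' @return A list: `defects` and `perikymata` record tibbles and a `truth`
#'   list (specimen effects, per-tooth true perikymata medians, per-defect
#'   true severities, the group table and seed).
#' @export
generate_cohort <- function(groups,
                            teeth_per_specimen = 2,
                            defects_per_tooth = 2,
                            pk_per_tooth = 10,
                            tooth_types = c("LC", "LI1"),
                            specimen_sd = 0.3,
                            tooth_sd = 0.2,
                            pk_rep_sd = 0.15,
                            severity_sd = 0.35,
                            defect_noise_sd = 0.1,
                            fallback_fraction = 12 / 71,
                            seed = 1L) {
  groups <- tibble::as_tibble(groups)
  need <- c("taxon", "temporal_group", "n_specimens", "pk_depth_mean",
            "severity_mean")
  if (nrow(groups) == 0) ed_stop("need at least one group", "ed_spec")
  if (!all(need %in% names(groups))) {
    ed_stop(paste("groups need columns:",
                  paste(setdiff(need, names(groups)), collapse = ", ")),
            "ed_spec")
  }
  if (any(groups$n_specimens < 1)) ed_stop("empty group", "ed_spec")
  if (fallback_fraction < 0 || fallback_fraction > 1) {
    ed_stop("fallback_fraction must be in [0, 1]", "ed_spec")
  }
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)

  canines <- c("LC", "UC")
  teeth <- list(); pk_recs <- list(); def_recs <- list()
  spec_fx <- list()
  sidx <- 0L
  for (gi in seq_len(nrow(groups))) {
    g <- groups[gi, ]
    for (j in seq_len(g$n_specimens)) {
      sidx <- sidx + 1L
      sid <- sprintf("S%03d", sidx)
      s_eff <- exp(rnorm(1, 0, specimen_sd))
      spec_fx[[sid]] <- s_eff
      for (t in seq_len(teeth_per_specimen)) {
        ttype <- tooth_types[(t - 1) %% length(tooth_types) + 1]
        pk_med <- g$pk_depth_mean * s_eff * exp(rnorm(1, 0, tooth_sd))
        preserved <- runif(1) >= fallback_fraction
        tid <- sprintf("%s_%s", sid, ttype)
        teeth[[length(teeth) + 1L]] <- tibble::tibble(
          tooth_id = tid, specimen_id = sid, taxon = g$taxon,
          temporal_group = g$temporal_group, tooth_type = ttype,
          tooth_class = if (ttype %in% canines) "canine" else "incisor",
          pk_median_true = pk_med, pk_preserved = preserved
        )
        if (preserved) {
          d <- pk_med * exp(rnorm(pk_per_tooth, 0, pk_rep_sd))
          pk_recs[[length(pk_recs) + 1L]] <- tibble::tibble(
            specimen_id = sid, taxon = g$taxon,
            temporal_group = g$temporal_group, tooth_type = ttype,
            tooth_class = if (ttype %in% canines) "canine" else "incisor",
            feature_kind = "perikyma",
            feature_id = sprintf("%s_pk%02d", tid, seq_len(pk_per_tooth)),
            depth_um = d, pk_preserved = TRUE
          )
        }
        sev <- g$severity_mean * exp(rnorm(defects_per_tooth, 0, severity_sd))
        dep <- sev * pk_med * exp(rnorm(defects_per_tooth, 0, defect_noise_sd))
        def_recs[[length(def_recs) + 1L]] <- tibble::tibble(
          specimen_id = sid, taxon = g$taxon,
          temporal_group = g$temporal_group, tooth_type = ttype,
          tooth_class = if (ttype %in% canines) "canine" else "incisor",
          feature_kind = "defect",
          feature_id = sprintf("%s_def%d", tid, seq_len(defects_per_tooth)),
          matched_group_id = sprintf("%s_m%d", sid, seq_len(defects_per_tooth)),
          depth_um = dep, severity_true = sev,
          pk_preserved = preserved
        )
      }
    }
  }
  teeth <- dplyr::bind_rows(teeth)
  defects <- dplyr::bind_rows(def_recs)
  perikymata <- if (length(pk_recs)) dplyr::bind_rows(pk_recs) else
    tibble::tibble()

  # guarantee a fallback pool: each (taxon, tooth_type) stratum keeps at
  # least one preserved tooth
  strat <- unique(teeth[, c("taxon", "tooth_type")])
  for (i in seq_len(nrow(strat))) {
    sel <- teeth$taxon == strat$taxon[i] & teeth$tooth_type == strat$tooth_type[i]
    if (!any(teeth$pk_preserved[sel])) {
      flip <- which(sel)[1]
      teeth$pk_preserved[flip] <- TRUE
      row <- teeth[flip, ]
      d <- row$pk_median_true * exp(rnorm(pk_per_tooth, 0, pk_rep_sd))
      perikymata <- dplyr::bind_rows(perikymata, tibble::tibble(
        specimen_id = row$specimen_id, taxon = row$taxon,
        temporal_group = row$temporal_group, tooth_type = row$tooth_type,
        tooth_class = row$tooth_class, feature_kind = "perikyma",
        feature_id = sprintf("%s_pk%02d", row$tooth_id, seq_len(pk_per_tooth)),
        depth_um = d, pk_preserved = TRUE
      ))
      defects$pk_preserved[defects$specimen_id == row$specimen_id &
                             defects$tooth_type == row$tooth_type] <- TRUE
    }
  }

  list(
    defects = defects,
    perikymata = perikymata,
    truth = list(
      teeth = teeth,
      specimen_effects = unlist(spec_fx),
      groups = groups,
      fallback_fraction = fallback_fraction,
      seed = seed
    )
  )
}
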