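#' Locate ridges and grooves on a profile with an amplitude threshold
#'
#' Sequential minimum-amplitude peak picking, the semantics of classic
#' FindPeaks-style tools: walking from the occlusal end, a running candidate
#' maximum is committed as a ridge as soon as the profile falls
#' `min_amplitude` below it, after which a running candidate minimum is
#' tracked and committed as a groove once the profile rises `min_amplitude`
#' above it, and so on. The retained extrema therefore strictly alternate
#' and every adjacent ridge-groove pair spans at least `min_amplitude`; a
#' pending candidate at the end of the profile that was never confirmed by a
#' full back-swing is not reported. Runs of equal elevation at a committed
#' extremum collapse to a single extremum at the plateau midpoint. With
#' `min_amplitude = 0` every strict local extremum is reported.
#'
#' `NA` samples (transect points over missing cells) are excluded from the
#' search. Raising `min_amplitude` never increases the number of retained
#' extrema.
#'
#' @param profile A `profile2d` from [extract_profile()] (or anything with a
#'   `samples` tibble of `distance` and `elevation`).
#' @param min_amplitude Minimum elevation span (um) between adjacent retained
#'   extrema; `>= 0`.
#' @return A `peak_set`: tibbles `maxima` and `minima`
#'   (`distance`, `elevation`), the alternating `extrema` table, and the
#'   threshold used.
#' @export
find_extrema <- function(profile, min_amplitude = 0) {
  if (min_amplitude < 0) ed_stop("min_amplitude must be >= 0", "ed_bad_param")
  s <- profile$samples
  s <- s[!is.na(s$elevation), ]
  if (nrow(s) < 8) {
    ed_stop("profile has fewer than 8 usable samples", "ed_bad_input")
  }
  ext <- delta_extrema(s$distance, s$elevation, min_amplitude)
  structure(
    list(
      maxima = ext[ext$type == "max", c("distance", "elevation")],
      minima = ext[ext$type == "min", c("distance", "elevation")],
      extrema = ext,
      min_amplitude = min_amplitude
    ),
    class = "peak_set"
  )
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set: %d maxima, %d minima (min_amplitude %.3g um)>\n",
              nrow(x$maxima), nrow(x$minima), x$min_amplitude))
  invisible(x)
}

# sequential delta-commit extremum detection (hysteresis peak picking).
# Plateau ties: the committed position is the midpoint of the contiguous run
# of samples equal to the extreme value at its first attainment.
delta_extrema <- function(dist, elev, delta) {
  n <- length(elev)
  plateau_mid <- function(i) {
    j <- i
    while (j < n && elev[j + 1L] == elev[i]) j <- j + 1L
    mean(dist[i:j])
  }
  out_d <- numeric(0); out_e <- numeric(0); out_t <- character(0)
  mx <- elev[1]; mn <- elev[1]; mxi <- 1L; mni <- 1L
  look_max <- TRUE
  for (i in seq_len(n)[-1]) {
    z <- elev[i]
    if (look_max) {
      if (z > mx) { mx <- z; mxi <- i }
      if (z < mx - delta) {
        out_d <- c(out_d, plateau_mid(mxi))
        out_e <- c(out_e, mx); out_t <- c(out_t, "max")
        mn <- z; mni <- i
        look_max <- FALSE
      }
    } else {
      if (z < mn) { mn <- z; mni <- i }
      if (z > mn + delta) {
        out_d <- c(out_d, plateau_mid(mni))
        out_e <- c(out_e, mn); out_t <- c(out_t, "min")
        mx <- z; mxi <- i
        look_max <- TRUE
      }
    }
  }
  # the walk starts ridge-seeking, so a profile that first descends commits
  # its occlusal end as the first ridge (defect transects start on the
  # occlusal shoulder)
  tibble::tibble(distance = out_d, elevation = out_e, type = out_t)
}

#' Measure maximum defect depth on a profile
#'
#' Implements the furrow-depth convention: depth is the elevation of the
#' occlusal-side shoulder minus the elevation of the deepest groove minimum
#' that survives amplitude thresholding. The occlusal shoulder is the nearest
#' retained maximum occlusal of the floor; if thresholding removed every
#' occlusal maximum (a smooth monotone flank), the highest profile sample
#' occlusal of the floor is used. The cervical shoulder is recorded for
#' audit but never used for the depth.
#'
#' @param profile A `profile2d` spanning both occlusal shoulders of exactly
#'   one target defect, occlusal end first.
#' @param min_amplitude Threshold (um) separating the defect from the
#'   surrounding perikymata ripple; default 5.
#' @param replicate Replicate index recorded on the measurement.
#' @return A one-row tibble: `feature_kind`, `depth_um`, shoulder and floor
#'   positions/elevations, cervical-shoulder audit fields, `replicate`.
#' @export
measure_defect_depth <- function(profile, min_amplitude = 5, replicate = 1L) {
  ps <- find_extrema(profile, min_amplitude)
  if (nrow(ps$minima) == 0) {
    ed_stop(paste0("no groove minimum survives thresholding: threshold too ",
                   "high or no defect present"), "ed_no_defect")
  }
  fl <- ps$minima[which.min(ps$minima$elevation), ]
  occl <- ps$maxima[ps$maxima$distance < fl$distance, ]
  s <- profile$samples[!is.na(profile$samples$elevation), ]
  if (nrow(occl) > 0) {
    sh <- occl[nrow(occl), ]  # nearest retained maximum occlusal of floor
  } else {
    pre <- s[s$distance < fl$distance, ]
    if (nrow(pre) == 0) ed_stop("no samples occlusal of floor", "ed_no_defect")
    sh <- pre[which.max(pre$elevation), c("distance", "elevation")]
  }
  cerv <- ps$maxima[ps$maxima$distance > fl$distance, ]
  if (nrow(cerv) > 0) {
    cv <- cerv[1, ]
  } else {
    post <- s[s$distance > fl$distance, ]
    cv <- if (nrow(post) > 0) post[which.max(post$elevation),
                                   c("distance", "elevation")]
          else tibble::tibble(distance = NA_real_, elevation = NA_real_)
  }
  depth <- sh$elevation - fl$elevation
  if (!is.finite(depth) || depth <= 0) {
    ed_stop("occlusal shoulder does not rise above the defect floor",
            "ed_no_defect")
  }
  tibble::tibble(
    feature_kind = "defect",
    depth_um = depth,
    shoulder_distance = sh$distance, shoulder_elevation = sh$elevation,
    floor_distance = fl$distance, floor_elevation = fl$elevation,
    cervical_shoulder_distance = cv$distance,
    cervical_shoulder_elevation = cv$elevation,
    min_amplitude = min_amplitude,
    replicate = as.integer(replicate)
  )
}

#' Measure perikymata depths along a profile
#'
#' For each retained groove minimum, depth is the elevation of an adjacent
#' ridge maximum minus the groove elevation. The default `ridge = "higher"`
#' convention takes the higher of the two adjacent ridges (the maximum
#' groove-to-ridge difference); `ridge = "occlusal"` restricts to the
#' occlusal-side ridge, matching the defect-shoulder convention. The ridge
#' side actually used is recorded in every measurement.
#'
#' @param profile A `profile2d` across perikymata on a relatively flat crown
#'   area without obvious defects (caller-asserted), occlusal end first.
#' @param n_target Number of grooves requested; fewer available grooves
#'   produce a shortfall warning, not an error.
#' @param min_amplitude Threshold in um; default 0.2, below typical
#'   perikymata depths so normal increments are retained.
#' @param ridge Ridge convention, `"higher"` (default) or `"occlusal"`.
#' @return A tibble with one row per measured groove, in transect order:
#'   `feature_kind`, `depth_um`, ridge and groove positions/elevations,
#'   `ridge_side`, `replicate`.
#' @export
measure_perikymata_depths <- function(profile, n_target = 4,
                                      min_amplitude = 0.2,
                                      ridge = c("higher", "occlusal"),
                                      replicate = 1L) {
  ridge <- match.arg(ridge)
  if (n_target < 1) ed_stop("n_target must be >= 1", "ed_bad_param")
  ps <- find_extrema(profile, min_amplitude)
  ext <- ps$extrema
  rows <- list()
  min_idx <- which(ext$type == "min")
  for (i in min_idx) {
    occ <- if (i > 1 && ext$type[i - 1] == "max") ext[i - 1, ] else NULL
    cer <- if (i < nrow(ext) && ext$type[i + 1] == "max") ext[i + 1, ] else NULL
    if (ridge == "occlusal") {
      if (is.null(occ)) next
      rg <- occ; side <- "occlusal"
    } else {
      if (is.null(occ) && is.null(cer)) next
      if (is.null(cer) || (!is.null(occ) && occ$elevation >= cer$elevation)) {
        rg <- occ; side <- "occlusal"
      } else {
        rg <- cer; side <- "cervical"
      }
    }
    depth <- rg$elevation - ext$elevation[i]
    if (!is.finite(depth) || depth <= 0) next
    rows[[length(rows) + 1L]] <- tibble::tibble(
      feature_kind = "perikyma",
      depth_um = depth,
      ridge_distance = rg$distance, ridge_elevation = rg$elevation,
      groove_distance = ext$distance[i], groove_elevation = ext$elevation[i],
      ridge_side = side,
      min_amplitude = min_amplitude,
      replicate = as.integer(replicate)
    )
    if (length(rows) == n_target) break
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else tibble::tibble(
    feature_kind = character(), depth_um = numeric(),
    ridge_distance = numeric(), ridge_elevation = numeric(),
    groove_distance = numeric(), groove_elevation = numeric(),
    ridge_side = character(), min_amplitude = numeric(),
    replicate = integer()
  )
  if (nrow(out) < n_target) {
    ed_warn(sprintf("only %d of %d requested perikymata measurable",
                    nrow(out), n_target), "ed_shortfall")
  }
  out
}

#' Aggregate replicate measurements of one feature
#'
#' Arithmetic mean across replicates (the triplicate-transect protocol's
#' depth of record), with count and range.
#'
#' @param measurements A tibble of depth measurements sharing one
#'   `feature_kind` (and one feature identity).
#' @return A one-row tibble: `feature_kind`, `n`, `mean_depth_um`,
#'   `min_depth_um`, `max_depth_um`, `range_um`.
#' @export
aggregate_feature <- function(measurements) {
  measurements <- tibble::as_tibble(measurements)
  if (nrow(measurements) == 0) {
    ed_stop("cannot aggregate zero measurements", "ed_aggregation")
  }
  if (length(unique(measurements$feature_kind)) != 1) {
    ed_stop("measurements must share one feature_kind", "ed_aggregation")
  }
  d <- measurements$depth_um
  tibble::tibble(
    feature_kind = measurements$feature_kind[1],
    n = length(d),
    mean_depth_um = mean(d),
    min_depth_um = min(d),
    max_depth_um = max(d),
    range_um = max(d) - min(d)
  )
}
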