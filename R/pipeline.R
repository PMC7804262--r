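#' Triplicate defect measurement on a DEM
#'
#' Runs the replicate-transect protocol: `n` parallel transects across the
#' defect, one depth measurement per transect, one row per replicate.
#' A shoulder-level quality check warns when the occlusal and cervical
#' shoulders differ by more than `level_tolerance` times the measured depth
#' (transects are supposed to be placed where the surface is level on either
#' side of the defect).
#'
#' @param d A [dem()].
#' @param tr Base [transect()] across the defect.
#' @param n Number of replicate transects (default 3).
#' @param lateral_offset Replicate spacing, um (default 25).
#' @param min_amplitude Defect amplitude threshold, um (default 5).
#' @param level_tolerance Shoulder-difference fraction triggering the
#'   unlevel-transect warning (default 0.5).
#' @param feature_id Identifier stamped on the rows.
#' @return Tibble of replicate measurements (see [measure_defect_depth()])
#'   with `feature_id` and transect endpoints added.
#' @export
measure_defect_replicates <- function(d, tr, n = 3, lateral_offset = 25,
                                      min_amplitude = 5,
                                      level_tolerance = 0.5,
                                      feature_id = "defect") {
  trs <- replicate_transects(tr, n = n, lateral_offset = lateral_offset, d = d)
  rows <- lapply(seq_along(trs), function(i) {
    p <- extract_profile(d, trs[[i]])
    m <- measure_defect_depth(p, min_amplitude = min_amplitude, replicate = i)
    m$feature_id <- feature_id
    m$transect_x0 <- trs[[i]]$start[1]; m$transect_y0 <- trs[[i]]$start[2]
    m$transect_x1 <- trs[[i]]$end[1];   m$transect_y1 <- trs[[i]]$end[2]
    m
  })
  out <- dplyr::bind_rows(rows)
  unlevel <- is.finite(out$cervical_shoulder_elevation) &
    abs(out$shoulder_elevation - out$cervical_shoulder_elevation) >
      level_tolerance * out$depth_um
  if (any(unlevel)) {
    ed_warn(sprintf(
      "%d replicate(s) have shoulders differing by more than %.0f%% of depth (unlevel transect?)",
      sum(unlevel), 100 * level_tolerance), "ed_unlevel")
  }
  out
}

#' Perikymata measurement on a DEM
#'
#' Extracts one transect across a flat perikymata field and measures up to
#' `n_target` groove depths.
#'
#' @param d A [dem()].
#' @param tr A [transect()] across perikymata.
#' @param n_target Number of grooves requested (default 10, the per-tooth
#'   protocol count).
#' @param min_amplitude Perikymata amplitude threshold, um (default 0.2).
#' @param ridge Ridge convention, see [measure_perikymata_depths()].
#' @param feature_prefix Prefix for per-groove feature ids.
#' @return Tibble of perikymata measurements with `feature_id` and transect
#'   endpoints added.
#' @export
measure_perikymata_transect <- function(d, tr, n_target = 10,
                                        min_amplitude = 0.2,
                                        ridge = c("higher", "occlusal"),
                                        feature_prefix = "pk") {
  ridge <- match.arg(ridge)
  p <- extract_profile(d, tr)
  m <- measure_perikymata_depths(p, n_target = n_target,
                                 min_amplitude = min_amplitude, ridge = ridge)
  if (nrow(m) > 0) {
    m$feature_id <- sprintf("%s%02d", feature_prefix, seq_len(nrow(m)))
    m$transect_x0 <- tr$start[1]; m$transect_y0 <- tr$start[2]
    m$transect_x1 <- tr$end[1];   m$transect_y1 <- tr$end[2]
  }
  m
}
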