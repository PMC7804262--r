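#' Raw-versus-leveled depth comparison on one surface
#'
#' Runs the full leveling-bias experiment on a synthetic crown surface:
#' measures defect depths (triplicate transects, replicate mean) and
#' perikymata depths on the raw DEM, then refits and removes each requested
#' form and re-measures the identical transects. Perikymata are taken from
#' the `n_pk` defect-free growth increments nearest the crown apex -- the
#' flattest part of the raw field, mirroring the protocol of drawing
#' perikymata transects across level areas -- and grooves are re-identified
#' after leveling by position (nearest groove within half the local spacing);
#' grooves displaced further than that are dropped from the pairing.
#'
#' @param surface Result of [generate_surface()].
#' @param forms Character vector of forms to remove, subset of
#'   `c("plane", "sphere")`.
#' @param n_pk Number of perikymata grooves to compare (default 3).
#' @param min_amplitude_defect,min_amplitude_pk Amplitude thresholds (um).
#' @return A list with one element per form, each a [leveling_bias()] report,
#'   plus `paired`: a tibble of all (form, feature, raw, leveled) rows.
#' @export
leveling_comparison <- function(surface, forms = c("plane", "sphere"),
                                n_pk = 3, min_amplitude_defect = 5,
                                min_amplitude_pk = 0.2) {
  forms <- match.arg(forms, several.ok = TRUE)
  tr <- surface$truth
  spec <- tr$spec
  d_raw <- surface$dem
  x_mid <- spec$extent[1] / 2
  y_apex <- spec$apex_frac * spec$extent[2]
  spacing <- spec$perikymata$mean_spacing

  # perikymata transect: n_pk free interior grooves nearest the apex
  free <- tr$perikymata[!tr$perikymata$in_defect, ]
  if (nrow(free) < n_pk) {
    ed_stop("not enough defect-free perikymata for the comparison",
            "ed_bad_input")
  }
  free <- free[order(abs(free$y_trough - y_apex)), ][seq_len(n_pk), ]
  # pad by one spacing each side so every compared groove keeps both adjacent
  # ridges even after leveling-induced tilt displaces the extrema, but stay
  # clear of any defect window
  y_lo <- max(0, min(free$y_occlusal_ridge) - spacing)
  y_hi <- min(spec$extent[2], max(free$y_cervical_ridge) + spacing)
  if (nrow(tr$defects) > 0) {
    for (j in seq_len(nrow(tr$defects))) {
      wlo <- tr$defects$center[j] - tr$defects$width[j]
      whi <- tr$defects$center[j] + tr$defects$width[j]
      if (y_hi > wlo && y_lo < wlo) y_hi <- min(y_hi, wlo - 5)
      if (y_lo < whi && y_hi > whi) y_lo <- max(y_lo, whi + 5)
    }
  }
  pk_tr <- transect(c(x_mid, y_lo), c(x_mid, y_hi), occlusal_end = "start")

  def_trs <- lapply(tr$defects$defect_id, function(id) {
    suggest_transect(surface, "defect", defect_id = id)
  })

  measure_all <- function(d) {
    defs <- dplyr::bind_rows(lapply(seq_along(def_trs), function(i) {
      m <- suppressWarnings(measure_defect_replicates(
        d, def_trs[[i]], min_amplitude = min_amplitude_defect,
        feature_id = tr$defects$defect_id[i]))
      agg <- aggregate_feature(m)
      tibble::tibble(feature_id = tr$defects$defect_id[i],
                     feature_kind = "defect", depth_um = agg$mean_depth_um)
    }))
    pks <- suppressWarnings(measure_perikymata_transect(
      d, pk_tr, n_target = n_pk + 2, min_amplitude = min_amplitude_pk))
    list(defects = defs, pk = pks)
  }

  raw <- measure_all(d_raw)
  # keep only the raw grooves that realise the n_pk selected near-apex
  # increments (the padded transect may pick up extra, more tilted grooves)
  if (nrow(raw$pk) > 0) {
    sel_y <- free$y_trough - pk_tr$start[2]
    keep <- vapply(seq_len(nrow(raw$pk)), function(i) {
      any(abs(raw$pk$groove_distance[i] - sel_y) <= spacing / 2)
    }, logical(1))
    raw$pk <- raw$pk[keep, ]
  }
  out <- list()
  paired <- list()
  for (fk in forms) {
    lev <- measure_all(remove_form(d_raw, fit_form(d_raw, fk)))
    # defects pair by id; grooves pair by position
    rows <- dplyr::inner_join(
      dplyr::select(raw$defects, "feature_id", "feature_kind",
                    raw_depth = "depth_um"),
      dplyr::select(lev$defects, "feature_id", leveled_depth = "depth_um"),
      by = "feature_id"
    )
    if (nrow(raw$pk) > 0 && nrow(lev$pk) > 0) {
      for (i in seq_len(nrow(raw$pk))) {
        j <- which.min(abs(lev$pk$groove_distance -
                             raw$pk$groove_distance[i]))
        if (abs(lev$pk$groove_distance[j] - raw$pk$groove_distance[i]) <=
            spacing / 2) {
          rows <- dplyr::bind_rows(rows, tibble::tibble(
            feature_id = sprintf("pk_groove_%02d", i),
            feature_kind = "perikyma",
            raw_depth = raw$pk$depth_um[i],
            leveled_depth = lev$pk$depth_um[j]
          ))
        }
      }
    }
    ra <- tibble::tibble(feature_id = rows$feature_id,
                         feature_kind = rows$feature_kind,
                         depth_um = rows$raw_depth)
    lv <- tibble::tibble(feature_id = rows$feature_id,
                         feature_kind = rows$feature_kind,
                         depth_um = rows$leveled_depth)
    out[[fk]] <- leveling_bias(ra, lv)
    rows$form_kind <- fk
    paired[[fk]] <- rows
  }
  out$paired <- dplyr::bind_rows(paired)
  out
}
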