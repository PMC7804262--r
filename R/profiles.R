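#' Define a transect across a DEM
#'
#' A straight segment along which an elevation profile is extracted, drawn
#' orthogonal to the feature of interest (across the occlusal shoulders of a
#' defect, or across several perikymata). `occlusal_end` records which end of
#' the segment points toward the cusp so extracted profiles can be oriented
#' occlusal-end-first.
#'
#' @param start,end Length-2 numeric, (x, y) endpoints in um.
#' @param sampling_step Sample spacing along the segment in um; `NULL` means
#'   "use the DEM's pixel pitch" at extraction time.
#' @param occlusal_end `"start"` or `"end"`.
#' @return A `transect` object.
#' @export
transect <- function(start, end, sampling_step = NULL,
                     occlusal_end = c("start", "end")) {
  occlusal_end <- match.arg(occlusal_end)
  start <- as.numeric(start); end <- as.numeric(end)
  if (length(start) != 2 || length(end) != 2 ||
      any(!is.finite(c(start, end)))) {
    ed_stop("transect endpoints must be finite (x, y) pairs", "ed_bad_input")
  }
  len <- sqrt(sum((end - start)^2))
  if (len <= 0) ed_stop("transect length must be > 0", "ed_bad_input")
  if (!is.null(sampling_step) && sampling_step <= 0) {
    ed_stop("sampling_step must be > 0", "ed_bad_input")
  }
  structure(
    list(start = start, end = end, sampling_step = sampling_step,
         occlusal_end = occlusal_end, length = len),
    class = "transect"
  )
}

#' @export
print.transect <- function(x, ...) {
  cat(sprintf("<transect (%.1f, %.1f) -> (%.1f, %.1f), %.1f um, occlusal at %s>\n",
              x$start[1], x$start[2], x$end[1], x$end[2], x$length,
              x$occlusal_end))
  invisible(x)
}

#' Serialise transects to / from JSON
#' @param transects A `transect` or list of them.
#' @param path JSON file path.
#' @return `read_transects` returns a list of `transect` objects.
#' @export
write_transects <- function(transects, path) {
  if (inherits(transects, "transect")) transects <- list(transects)
  jsonlite::write_json(
    lapply(transects, function(t) {
      list(start = t$start, end = t$end,
           sampling_step = t$sampling_step, occlusal_end = t$occlusal_end)
    }),
    path, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' @rdname write_transects
#' @export
read_transects <- function(path) {
  xs <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(xs, function(t) {
    transect(as.numeric(unlist(t$start)), as.numeric(unlist(t$end)),
             sampling_step = if (is.null(t$sampling_step)) NULL else
               as.numeric(t$sampling_step),
             occlusal_end = t$occlusal_end)
  })
}

# NA-aware bilinear sampling of a DEM at arbitrary (x, y) positions.
# A sample is NA if it falls outside the grid or any neighbouring cell with
# nonzero interpolation weight is missing.
dem_bilinear <- function(d, px, py) {
  xs <- dem_x(d); ys <- dem_y(d)
  gx <- (px - d$origin[1]) / d$pixel_pitch
  gy <- (py - d$origin[2]) / d$pixel_pitch
  # snap to grid nodes within rounding noise so node-aligned samples are exact
  gx <- ifelse(abs(gx - round(gx)) < 1e-9, round(gx), gx)
  gy <- ifelse(abs(gy - round(gy)) < 1e-9, round(gy), gy)
  nc <- ncol(d$z); nr <- nrow(d$z)
  out <- rep(NA_real_, length(px))
  eps <- 1e-9
  inside <- gx >= -eps & gx <= nc - 1 + eps & gy >= -eps & gy <= nr - 1 + eps
  if (!any(inside)) return(out)
  gx <- pmin(pmax(gx[inside], 0), nc - 1)
  gy <- pmin(pmax(gy[inside], 0), nr - 1)
  j0 <- pmin(floor(gx), nc - 2); i0 <- pmin(floor(gy), nr - 2)
  fx <- gx - j0; fy <- gy - i0
  idx <- function(i, j) i + 1L + nr * j  # 1-based linear index into z
  w00 <- (1 - fx) * (1 - fy); z00 <- d$z[idx(i0, j0)]
  w10 <- (1 - fx) * fy;       z10 <- d$z[idx(i0 + 1, j0)]
  w01 <- fx * (1 - fy);       z01 <- d$z[idx(i0, j0 + 1)]
  w11 <- fx * fy;             z11 <- d$z[idx(i0 + 1, j0 + 1)]
  acc <- w00 * ifelse(w00 > eps, z00, 0) + w10 * ifelse(w10 > eps, z10, 0) +
    w01 * ifelse(w01 > eps, z01, 0) + w11 * ifelse(w11 > eps, z11, 0)
  bad <- (w00 > eps & is.na(z00)) | (w10 > eps & is.na(z10)) |
    (w01 > eps & is.na(z01)) | (w11 > eps & is.na(z11))
  acc[bad] <- NA_real_
  out[inside] <- acc
  out
}

#' Extract an elevation profile along a transect
#'
#' Elevations are bilinearly interpolated at equally spaced points from start
#' to end inclusive. Samples crossing missing cells are kept as `NA`
#' elevations (flagged, and excluded from extremum search downstream). The
#' returned profile is ordered so its occlusal end is at distance 0.
#'
#' @param d A [dem()].
#' @param tr A [transect()]; a sampling step of `NULL` defaults to the DEM's
#'   pixel pitch.
#' @return A `profile2d`: a list with a `samples` tibble
#'   (`distance`, `elevation` in um), the transect, and provenance.
#' @export
extract_profile <- function(d, tr) {
  stopifnot(inherits(d, "dem"), inherits(tr, "transect"))
  step <- tr$sampling_step %||% d$pixel_pitch
  n <- max(2L, floor(tr$length / step + 1e-9) + 1L)
  tseq <- seq(0, 1, length.out = n)
  px <- tr$start[1] + tseq * (tr$end[1] - tr$start[1])
  py <- tr$start[2] + tseq * (tr$end[2] - tr$start[2])
  elev <- dem_bilinear(d, px, py)
  if (mean(is.na(elev)) > 0.2) {
    ed_stop(sprintf("unusable transect: %.0f%% of samples on missing cells",
                    100 * mean(is.na(elev))), "ed_unusable_transect")
  }
  dist <- tseq * tr$length
  if (tr$occlusal_end == "end") {
    elev <- rev(elev)
    dist <- rev(tr$length - dist)
  }
  structure(
    list(
      samples = tibble::tibble(distance = dist, elevation = elev),
      transect = tr,
      provenance = d$provenance
    ),
    class = "profile2d"
  )
}

#' @export
print.profile2d <- function(x, ...) {
  cat(sprintf("<profile2d: %d samples over %.1f um, occlusal end first>\n",
              nrow(x$samples), max(x$samples$distance)))
  invisible(x)
}

#' @export
plot.profile2d <- function(x, ...) {
  plot(x$samples$distance, x$samples$elevation, type = "l",
       xlab = "distance from occlusal end (um)", ylab = "elevation (um)", ...)
  invisible(x)
}

#' Build parallel replicate transects
#'
#' Returns `n` transects parallel to `base`, centred on it and separated by
#' `lateral_offset` (default 25 um, chosen to stay within a single defect's
#' lateral extent), with identical length and orientation. Used for the
#' triplicate defect-depth measurements.
#'
#' @param base A [transect()].
#' @param n Number of replicates (`>= 1`).
#' @param lateral_offset Spacing between adjacent transects, um.
#' @param d Optional [dem()]; when given, an offset that pushes any replicate
#'   off the DEM extent raises a geometry error.
#' @return A list of `transect` objects.
#' @export
replicate_transects <- function(base, n = 3, lateral_offset = 25, d = NULL) {
  stopifnot(inherits(base, "transect"))
  if (n < 1) ed_stop("n must be >= 1", "ed_bad_param")
  dir <- (base$end - base$start) / base$length
  normal <- c(dir[2], -dir[1])
  offsets <- (seq_len(n) - (n + 1) / 2) * lateral_offset
  out <- lapply(offsets, function(o) {
    transect(base$start + o * normal, base$end + o * normal,
             sampling_step = base$sampling_step,
             occlusal_end = base$occlusal_end)
  })
  if (!is.null(d)) {
    stopifnot(inherits(d, "dem"))
    xr <- range(dem_x(d)); yr <- range(dem_y(d))
    for (t in out) {
      pts <- rbind(t$start, t$end)
      if (any(pts[, 1] < xr[1] - 1e-9 | pts[, 1] > xr[2] + 1e-9 |
              pts[, 2] < yr[1] - 1e-9 | pts[, 2] > yr[2] + 1e-9)) {
        ed_stop("replicate transect falls outside the DEM extent",
                "ed_geometry")
      }
    }
  }
  out
}
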