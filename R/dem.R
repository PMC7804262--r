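#' Construct a digital elevation model (DEM)
#'
#' A DEM is a regular grid of surface heights in micrometres. Rows index the
#' y axis (row `i` sits at `origin[2] + (i - 1) * pixel_pitch`), columns the x
#' axis. Missing cells (outside the convex hull of the measured points, or
#' instrument dropouts) are `NA`; no magic elevation code is used.
#'
#' `occlusal_axis` records which grid direction points toward the cusp:
#' `"row-"`/`"row+"` (decreasing / increasing row index) or
#' `"col-"`/`"col+"`.
#'
#' @param z Numeric matrix of elevations (um), `NA` for missing cells.
#' @param pixel_pitch Grid pitch in um/pixel, uniform in x and y.
#' @param origin Length-2 numeric, (x, y) of cell `[1, 1]` in um.
#' @param occlusal_axis One of `"row-"`, `"row+"`, `"col-"`, `"col+"`.
#' @param provenance Character vector: source id and processing history.
#' @return An object of class `dem`.
#' @export
dem <- function(z, pixel_pitch, origin = c(0, 0), occlusal_axis = "row-",
                provenance = character()) {
  z <- as.matrix(z)
  if (nrow(z) < 2 || ncol(z) < 2) {
    ed_stop("DEM grid needs at least 2 rows and 2 columns", "ed_bad_input")
  }
  if (!is.numeric(pixel_pitch) || pixel_pitch <= 0) {
    ed_stop("pixel_pitch must be > 0", "ed_bad_input")
  }
  if (any(is.infinite(z) | is.nan(z), na.rm = TRUE)) {
    ed_stop("non-missing DEM cells must be finite", "ed_bad_input")
  }
  if (!occlusal_axis %in% c("row-", "row+", "col-", "col+")) {
    ed_stop("invalid occlusal_axis", "ed_bad_input")
  }
  structure(
    list(z = z, pixel_pitch = pixel_pitch, origin = as.numeric(origin),
         occlusal_axis = occlusal_axis, provenance = as.character(provenance)),
    class = "dem"
  )
}

#' @export
print.dem <- function(x, ...) {
  cat(sprintf(
    "<dem %d x %d cells, pitch %.3g um, %.1f%% measured, occlusal %s>\n",
    nrow(x$z), ncol(x$z), x$pixel_pitch, 100 * mean(!is.na(x$z)),
    x$occlusal_axis
  ))
  invisible(x)
}

# x and y node coordinates of a DEM
dem_x <- function(d) d$origin[1] + (seq_len(ncol(d$z)) - 1) * d$pixel_pitch
dem_y <- function(d) d$origin[2] + (seq_len(nrow(d$z)) - 1) * d$pixel_pitch

#' Interpolate a point cloud onto a regular elevation grid
#'
#' Grids the measured points of a cloud by piecewise-linear (barycentric)
#' interpolation over their Delaunay triangulation, the behaviour of the
#' classic XYZ-to-DEM import step. The grid spans the bounding box of the
#' measured points; nodes outside their convex hull are missing; nodes
#' coincident with an input point reproduce its z exactly. No extrapolation
#' beyond the hull is ever performed.
#'
#' Exact duplicate (x, y) positions keep the last-read z with a warning.
#'
#' @param cloud A [point_cloud()].
#' @param pixel_pitch Target grid pitch, um/pixel (default 0.64, the lateral
#'   resolution of the reference instrument).
#' @param occlusal_axis Orientation tag stored on the result.
#' @return A [dem()].
#' @export
interpolate_dem <- function(cloud, pixel_pitch = 0.64, occlusal_axis = "row-") {
  stopifnot(inherits(cloud, "point_cloud"))
  if (pixel_pitch <= 0) ed_stop("pixel_pitch must be > 0", "ed_bad_input")
  p <- cloud$points[cloud$points$measured, ]
  if (nrow(p) < 3) {
    ed_stop("need at least 3 measured points", "ed_bad_input")
  }
  dup <- duplicated(cbind(p$x, p$y), fromLast = TRUE)
  if (any(dup)) {
    ed_warn(sprintf("%d duplicate (x, y) positions: keeping last-read z",
                    sum(dup)), "ed_duplicates")
    p <- p[!dup, ]
  }
  rx <- range(p$x); ry <- range(p$y)
  if (diff(rx) < pixel_pitch || diff(ry) < pixel_pitch) {
    ed_stop("point extent smaller than one pixel", "ed_bad_input")
  }
  xo <- rx[1] + pixel_pitch * (0:floor(diff(rx) / pixel_pitch + 1e-9))
  yo <- ry[1] + pixel_pitch * (0:floor(diff(ry) / pixel_pitch + 1e-9))
  g <- tryCatch(
    interp::interp(p$x, p$y, p$z, xo = xo, yo = yo, method = "linear",
                   extrap = FALSE, duplicate = "error"),
    error = function(e) {
      ed_stop(paste0("Delaunay triangulation failed (degenerate point ",
                     "configuration?): ", conditionMessage(e)),
              "ed_degenerate")
    }
  )
  dem(
    z = t(g$z),  # interp returns z[x, y]; DEM stores rows = y
    pixel_pitch = pixel_pitch,
    origin = c(rx[1], ry[1]),
    occlusal_axis = occlusal_axis,
    provenance = c(cloud$source_id,
                   sprintf("interpolate_dem(pitch=%g)", pixel_pitch))
  )
}

#' Flip a DEM vertically
#'
#' Reverses the row order (the y axis) and updates the occlusal-axis tag
#' consistently: imported DEMs arrive upside-down relative to the drawing
#' convention and are flipped before analysis. Applying the flip twice
#' restores the original DEM.
#'
#' @param d A [dem()].
#' @return The flipped [dem()].
#' @export
flip_vertical <- function(d) {
  stopifnot(inherits(d, "dem"))
  flip_map <- c("row-" = "row+", "row+" = "row-",
                "col-" = "col-", "col+" = "col+")
  d$z <- d$z[rev(seq_len(nrow(d$z))), , drop = FALSE]
  d$occlusal_axis <- unname(flip_map[d$occlusal_axis])
  d$provenance <- c(d$provenance, "flip_vertical")
  d
}

#' Remove spike noise from a DEM
#'
#' Robust outlier filter: a cell deviating from its window median by more than
#' `k` times the normalised window MAD (1.4826 x median absolute deviation) is
#' replaced by that window median; all other cells are left untouched. Missing
#' cells are ignored in the window statistics and stay missing. This mirrors
#' the "reduce noise" cleanup applied before collecting depth data when
#' spikes are visible in a scan.
#'
#' @param d A [dem()].
#' @param window Odd window edge length in pixels, `>= 3` (default 5).
#' @param k Threshold multiplier, `> 0` (default 3).
#' @return The filtered [dem()].
#' @export
reduce_noise <- function(d, window = 5, k = 3) {
  stopifnot(inherits(d, "dem"))
  if (window %% 2 != 1 || window < 3) {
    ed_stop("window must be odd and >= 3", "ed_bad_param")
  }
  if (k <= 0) ed_stop("k must be > 0", "ed_bad_param")
  nr <- nrow(d$z); nc <- ncol(d$z)
  if (window > nr || window > nc) {
    ed_stop("window larger than grid dimension", "ed_bad_param")
  }
  h <- (window - 1) / 2
  offs <- expand.grid(dr = -h:h, dc = -h:h)
  stack <- matrix(NA_real_, nrow = nr * nc, ncol = nrow(offs))
  for (j in seq_len(nrow(offs))) {
    dr <- offs$dr[j]; dc <- offs$dc[j]
    src_r <- seq_len(nr) + dr
    src_c <- seq_len(nc) + dc
    ok_r <- src_r >= 1 & src_r <= nr
    ok_c <- src_c >= 1 & src_c <= nc
    m <- matrix(NA_real_, nr, nc)
    m[ok_r, ok_c] <- d$z[src_r[ok_r], src_c[ok_c]]
    stack[, j] <- as.vector(m)
  }
  med <- apply(stack, 1, median, na.rm = TRUE)
  madv <- apply(abs(stack - med), 1, median, na.rm = TRUE)
  z <- as.vector(d$z)
  dev <- abs(z - med)
  repl <- !is.na(z) & !is.na(med) & dev > k * 1.4826 * madv
  z[repl] <- med[repl]
  d$z <- matrix(z, nr, nc)
  d$provenance <- c(d$provenance,
                    sprintf("reduce_noise(window=%d, k=%g, replaced=%d)",
                            window, k, sum(repl)))
  d
}

#' Fraction of measured points
#'
#' Measured count divided by total count, in `[0, 1]`. Well-configured scans
#' of epoxy tooth replicas reach 0.98-0.999.
#'
#' @param x A [point_cloud()] or [dem()].
#' @return A proportion.
#' @export
measured_fraction <- function(x) UseMethod("measured_fraction")

#' @export
measured_fraction.point_cloud <- function(x) mean(x$points$measured)

#' @export
measured_fraction.dem <- function(x) mean(!is.na(x$z))

#' Export / import a DEM as CSV plus JSON sidecar
#'
#' The elevation grid is written as a plain CSV matrix (one row per grid row,
#' empty fields for missing cells); pitch, origin, orientation and provenance
#' go to a JSON sidecar at `<path>.json`.
#'
#' @param d A [dem()].
#' @param path CSV path (sidecar written at `paste0(path, ".json")`).
#' @return `read_dem` returns the [dem()].
#' @export
write_dem <- function(d, path) {
  stopifnot(inherits(d, "dem"))
  data.table::fwrite(data.table::as.data.table(d$z), path,
                     col.names = FALSE, na = "")
  jsonlite::write_json(
    list(pixel_pitch = d$pixel_pitch, origin = d$origin,
         occlusal_axis = d$occlusal_axis, provenance = d$provenance,
         nrow = nrow(d$z), ncol = ncol(d$z)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_dem
#' @export
read_dem <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  z <- as.matrix(data.table::fread(path, header = FALSE, na.strings = ""))
  dimnames(z) <- NULL
  dem(z, pixel_pitch = meta$pixel_pitch, origin = as.numeric(meta$origin),
      occlusal_axis = meta$occlusal_axis,
      provenance = as.character(meta$provenance))
}

#' Convert a DEM to a point cloud
#'
#' One point per grid node; missing cells become unmeasured points with
#' `NA` z, so the measured fraction is preserved through the round trip.
#'
#' @param d A [dem()].
#' @param source_id Identifier for the resulting cloud.
#' @return A [point_cloud()].
#' @export
dem_to_cloud <- function(d, source_id = NULL) {
  stopifnot(inherits(d, "dem"))
  xs <- dem_x(d); ys <- dem_y(d)
  point_cloud(
    x = rep(xs, each = length(ys)),
    y = rep(ys, times = length(xs)),
    z = as.vector(d$z),
    source_id = source_id %||% (if (length(d$provenance)) d$provenance[1] else "dem"),
    lateral_pitch = d$pixel_pitch
  )
}
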