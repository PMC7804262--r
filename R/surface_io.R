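#' Construct a point cloud of surface samples
#'
#' A point cloud holds raw (x, y, z) surface samples in micrometres as exported
#' by a confocal profilometer, together with acquisition metadata. Unmeasured
#' points (dropouts where the instrument could not resolve a height) are kept
#' with `measured = FALSE` rather than dropped, so that the measured-point
#' fraction of a scan stays computable.
#'
#' @param x,y,z Numeric vectors of equal length; coordinates in micrometres.
#'   `z` may contain `NA` for unmeasured points.
#' @param source_id Character scalar identifying the scan.
#' @param lateral_pitch Optional lateral sampling pitch (um), `> 0`.
#' @param z_step Optional vertical scanning step (um), `> 0`.
#' @param measured Optional logical vector; defaults to `is.finite(z)`.
#' @return An object of class `point_cloud`: a list with a `points` tibble
#'   (`x`, `y`, `z`, `measured`) and the metadata fields.
#' @export
point_cloud <- function(x, y, z, source_id = "cloud",
                        lateral_pitch = NULL, z_step = NULL, measured = NULL) {
  n <- length(x)
  if (length(y) != n || length(z) != n) {
    ed_stop("x, y and z must have equal length", "ed_bad_input")
  }
  if (is.null(measured)) measured <- is.finite(z)
  if (length(measured) != n) {
    ed_stop("measured flags must match point count", "ed_bad_input")
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    ed_stop("all x and y coordinates must be finite", "ed_bad_input")
  }
  if (any(measured & !is.finite(z))) {
    ed_stop("measured points must have finite z", "ed_bad_input")
  }
  if (!is.null(lateral_pitch) && lateral_pitch <= 0) {
    ed_stop("lateral_pitch must be > 0", "ed_bad_input")
  }
  if (!is.null(z_step) && z_step <= 0) {
    ed_stop("z_step must be > 0", "ed_bad_input")
  }
  xy <- unique(cbind(x[measured], y[measured]))
  if (nrow(xy) >= 3) {
    # non-collinearity check on the measured (x, y) positions
    v1 <- xy[2, ] - xy[1, ]
    cross <- (xy[, 1] - xy[1, 1]) * v1[2] - (xy[, 2] - xy[1, 2]) * v1[1]
    span <- max(abs(xy)) + 1
    if (all(abs(cross) < 1e-9 * span^2)) {
      ed_stop("all (x, y) positions are collinear", "ed_degenerate")
    }
  }
  structure(
    list(
      points = tibble::tibble(x = as.numeric(x), y = as.numeric(y),
                              z = as.numeric(z), measured = as.logical(measured)),
      source_id = source_id,
      lateral_pitch = lateral_pitch,
      z_step = z_step
    ),
    class = "point_cloud"
  )
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud '%s': %d points, %.1f%% measured>\n",
              x$source_id, nrow(x$points), 100 * mean(x$points$measured)))
  invisible(x)
}

#' Scan acquisition metadata
#'
#' Records instrument settings and quality indicators for one profilometer
#' scan: lateral pixel pitch, vertical step, vertical range, field of view and
#' the fraction of points the instrument actually measured (well-set scans
#' reach 98-99.9%).
#'
#' @param pixel_pitch Lateral resolution, um/pixel (`> 0`).
#' @param z_step Vertical scanning step, um (default 1).
#' @param z_range Vertical range of the scan, um.
#' @param field_of_view Numeric length-2, (width, length) in um.
#' @param measured_fraction Proportion of measured points in `[0, 1]`.
#' @return A `scan_metadata` list.
#' @export
scan_metadata <- function(pixel_pitch = 0.64, z_step = 1, z_range = NA_real_,
                          field_of_view = c(NA_real_, NA_real_),
                          measured_fraction = NA_real_) {
  if (pixel_pitch <= 0) ed_stop("pixel_pitch must be > 0", "ed_bad_input")
  if (!is.na(measured_fraction) &&
      (measured_fraction < 0 || measured_fraction > 1)) {
    ed_stop("measured_fraction must be in [0, 1]", "ed_bad_input")
  }
  structure(
    list(pixel_pitch = pixel_pitch, z_step = z_step, z_range = z_range,
         field_of_view = field_of_view, measured_fraction = measured_fraction),
    class = "scan_metadata"
  )
}

#' Write / read scan metadata as a JSON sidecar
#' @param meta A [scan_metadata()] object.
#' @param path File path.
#' @return `read_scan_metadata` returns a `scan_metadata` object.
#' @export
write_scan_metadata <- function(meta, path) {
  jsonlite::write_json(unclass(meta), path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_scan_metadata
#' @export
read_scan_metadata <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  fov <- as.numeric(x$field_of_view %||% c(NA, NA))
  if (length(fov) < 2) fov <- c(fov, NA_real_)
  scan_metadata(
    pixel_pitch = as.numeric(x$pixel_pitch %||% 0.64),
    z_step = as.numeric(x$z_step %||% 1),
    z_range = as.numeric(x$z_range %||% NA),
    field_of_view = fov,
    measured_fraction = as.numeric(x$measured_fraction %||% NA)
  )
}

.unit_to_um <- c(um = 1, micron = 1, mm = 1e3, nm = 1e-3, m = 1e6)

#' Read an XYZ `.dat` point-cloud export
#'
#' Parses the delimited text format profilometers export: one point per line
#' with three numeric fields, optional `#` comment lines, and a delimiter that
#' is auto-detected (whitespace, comma or semicolon) but must be consistent
#' within the file. Lines whose z field is empty or equals `na_token` become
#' unmeasured points (`measured = FALSE`); they are never silently dropped, so
#' the measured-point percentage of the scan is preserved.
#'
#' @param path Path to the `.dat` file (or a character vector of lines via
#'   `text`).
#' @param units Length unit of the file; coordinates are converted to um.
#'   One of `"um"`, `"mm"`, `"nm"`, `"m"`.
#' @param columns Column order in the file, a permutation of
#'   `c("x", "y", "z")`.
#' @param na_token No-data token for the z field (besides an empty field);
#'   default `"NaN"`.
#' @param text Optional character vector of lines, used instead of `path`.
#' @param source_id Identifier stored on the cloud; defaults to the file name.
#' @return A [point_cloud()] with coordinates in micrometres.
#' @export
read_xyz_dat <- function(path = NULL, units = c("um", "mm", "nm", "m"),
                         columns = c("x", "y", "z"), na_token = "NaN",
                         text = NULL, source_id = NULL) {
  units <- match.arg(units)
  if (!setequal(columns, c("x", "y", "z")) || length(columns) != 3) {
    ed_stop("columns must be a permutation of c('x','y','z')", "ed_bad_input")
  }
  lines <- if (!is.null(text)) text else readLines(path, warn = FALSE)
  if (is.null(source_id)) {
    source_id <- if (!is.null(path)) basename(path) else "text"
  }
  keep <- !grepl("^\\s*(#|$)", lines)
  data_lines <- lines[keep]
  line_no <- which(keep)
  if (length(data_lines) == 0) {
    ed_stop("no data lines found", "ed_malformed")
  }

  # delimiter auto-detection from the first data line; mixed delimiters are a
  # format error (a comma file must not contain semicolons and vice versa)
  has_semi <- grepl(";", data_lines, fixed = TRUE)
  has_comma <- grepl(",", data_lines, fixed = TRUE)
  sep <- if (has_semi[1]) ";" else if (has_comma[1]) "," else " "
  if ((sep == ";" && any(has_comma)) ||
      (sep == "," && any(has_semi)) ||
      (sep == " " && any(has_semi | has_comma))) {
    ed_stop("mixed delimiters detected in .dat file", "ed_format")
  }

  if (sep == " ") data_lines <- gsub("[ \t]+", " ", trimws(data_lines))
  dt <- data.table::fread(
    text = data_lines, sep = sep, header = FALSE, fill = TRUE,
    na.strings = c(na_token, "", "NA"), colClasses = "character",
    strip.white = TRUE
  )
  if (ncol(dt) < 3) {
    # lines with fewer than 3 fields: pad so the z check below flags them
    for (j in seq_len(3 - ncol(dt))) dt[[ncol(dt) + 1L]] <- NA_character_
  }
  num <- lapply(dt[, 1:3], function(col) suppressWarnings(as.numeric(col)))
  names(num) <- columns
  bad_xy <- !is.finite(num$x) | !is.finite(num$y)
  z_chr <- dt[[match("z", columns)]]
  # z is "unmeasured" when it is the declared token / empty; any other
  # non-numeric z makes the line unparseable
  z_is_na_token <- is.na(z_chr)
  bad_z <- !z_is_na_token & !is.finite(num$z)
  bad <- bad_xy | bad_z
  n_valid <- sum(!bad)
  if (n_valid < 3) {
    first_bad <- if (any(bad)) line_no[which(bad)[1]] else NA_integer_
    ed_stop(sprintf(
      "fewer than 3 valid points (%d found)%s", n_valid,
      if (!is.na(first_bad)) sprintf("; first offending line: %d", first_bad) else ""
    ), "ed_malformed")
  }
  ok <- !bad
  f <- .unit_to_um[[units]]
  point_cloud(
    x = num$x[ok] * f, y = num$y[ok] * f, z = num$z[ok] * f,
    source_id = source_id,
    measured = is.finite(num$z[ok])
  )
}

#' Write a point cloud as XYZ `.dat` text
#'
#' Inverse of [read_xyz_dat()]: one `x y z` line per point (whitespace
#' delimited, full precision), unmeasured points written with the `na_token`
#' in the z field.
#'
#' @param cloud A [point_cloud()].
#' @param path Output path.
#' @param na_token Token written for unmeasured z values.
#' @return `path`, invisibly.
#' @export
write_xyz_dat <- function(cloud, path, na_token = "NaN") {
  stopifnot(inherits(cloud, "point_cloud"))
  p <- cloud$points
  zc <- ifelse(p$measured, format(p$z, digits = 17, trim = TRUE), na_token)
  lines <- paste(format(p$x, digits = 17, trim = TRUE),
                 format(p$y, digits = 17, trim = TRUE), zc)
  writeLines(lines, path)
  invisible(path)
}

.measurement_cols <- c(
  "specimen", "taxon", "site", "group", "tooth_type", "feature_kind",
  "feature_id", "replicate", "depth_um",
  "transect_x0", "transect_y0", "transect_x1", "transect_y1"
)

#' Write a depth-measurement table
#'
#' One row per replicate measurement (the triplicate transect structure of the
#' protocol is preserved; averaging across replicates is a downstream step,
#' see [aggregate_feature()]). Columns follow a fixed header so tables from
#' different runs concatenate cleanly.
#'
#' @param records A data frame with at least `feature_id`, `replicate` and
#'   `depth_um`; missing metadata columns are filled with `NA`.
#' @param path Output CSV path.
#' @return The completed tibble, invisibly.
#' @export
write_measurements <- function(records, path) {
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0) ed_stop("records must be nonempty", "ed_bad_input")
  for (col in .measurement_cols) {
    if (!col %in% names(records)) records[[col]] <- NA
  }
  records <- records[, .measurement_cols]
  dup <- duplicated(records[, c("feature_id", "replicate")])
  if (any(dup)) {
    ed_stop(sprintf("duplicate (feature_id, replicate) pairs: %s",
                    paste(unique(records$feature_id[dup]), collapse = ", ")),
            "ed_integrity")
  }
  readr::write_csv(records, path, na = "")
  invisible(records)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  readr::read_csv(
    path, na = "",
    col_types = readr::cols(
      specimen = "c", taxon = "c", site = "c", group = "c", tooth_type = "c",
      feature_kind = "c", feature_id = "c", replicate = "i", depth_um = "d",
      transect_x0 = "d", transect_y0 = "d", transect_x1 = "d", transect_y1 = "d"
    )
  )
}
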