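#' Fit a plane or sphere form to a DEM
#'
#' Whole-field least-squares form fitting, as used by profilometer software
#' "form removal" leveling. The plane `z = a + b*x + c*y` is an ordinary
#' least-squares fit over all non-missing cells. The sphere is initialised
#' with the algebraic (linearised) least-squares solution and refined by
#' iterative geometric least squares (Gauss-Newton on the orthogonal
#' residuals; convergence when the parameter step drops below 1e-6 um, at
#' most 100 iterations).
#'
#' @param d A [dem()].
#' @param form_kind `"plane"` or `"sphere"`.
#' @return A `form_params` object: `form_kind`, fitted coefficients
#'   (`plane = c(a, b, c)` or `center`, `radius`, `branch`), and `fit_rms`,
#'   the root-mean-square residual in um.
#' @export
fit_form <- function(d, form_kind = c("plane", "sphere")) {
  stopifnot(inherits(d, "dem"))
  form_kind <- match.arg(form_kind)
  xs <- dem_x(d); ys <- dem_y(d)
  ok <- !is.na(d$z)
  x <- rep(xs, each = nrow(d$z))[ok]
  y <- rep(ys, times = ncol(d$z))[ok]
  z <- d$z[ok]
  n <- length(z)

  if (form_kind == "plane") {
    if (n < 3) ed_stop("plane fit needs >= 3 non-missing cells", "ed_fit")
    X <- cbind(1, x, y)
    beta <- tryCatch(qr.coef(qr(X), z),
                     error = function(e) ed_stop("plane fit failed", "ed_fit"))
    if (any(is.na(beta))) ed_stop("degenerate plane fit", "ed_fit")
    res <- z - X %*% beta
    return(structure(
      list(form_kind = "plane",
           plane = setNames(as.numeric(beta), c("a", "b", "c")),
           fit_rms = sqrt(mean(res^2))),
      class = "form_params"
    ))
  }

  # sphere: algebraic initialisation, linear in (2cx, 2cy, 2cz, r^2 - |c|^2)
  if (n < 4) ed_stop("sphere fit needs >= 4 non-missing cells", "ed_fit")
  A <- cbind(2 * x, 2 * y, 2 * z, 1)
  b <- x^2 + y^2 + z^2
  sol <- tryCatch(qr.coef(qr(A), b),
                  error = function(e) ed_stop("sphere fit failed", "ed_fit"))
  if (any(is.na(sol))) {
    ed_stop("degenerate sphere fit (coplanar cells?)", "ed_fit")
  }
  ctr <- sol[1:3]
  r2 <- sol[4] + sum(ctr^2)
  if (!is.finite(r2) || r2 <= 0) {
    ed_stop("degenerate sphere fit (coplanar cells?)", "ed_fit")
  }
  r <- sqrt(r2)

  # geometric refinement
  par <- c(ctr, r)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    dx <- x - par[1]; dy <- y - par[2]; dz <- z - par[3]
    di <- sqrt(dx^2 + dy^2 + dz^2)
    di[di < 1e-12] <- 1e-12
    res <- di - par[4]
    J <- cbind(-dx / di, -dy / di, -dz / di, -1)
    step <- tryCatch(qr.coef(qr(J), -res), error = function(e) rep(0, 4))
    if (any(is.na(step))) step <- rep(0, 4)
    par <- par + step
    if (max(abs(step)) < 1e-6 || iter >= 100L) break
  }
  if (par[4] <= 0) ed_stop("sphere fit collapsed to nonpositive radius", "ed_fit")
  dx <- x - par[1]; dy <- y - par[2]; dz <- z - par[3]
  res <- sqrt(dx^2 + dy^2 + dz^2) - par[4]
  structure(
    list(form_kind = "sphere",
         center = setNames(par[1:3], c("x", "y", "z")),
         radius = par[4],
         branch = if (par[3] > mean(z)) -1 else 1,
         fit_rms = sqrt(mean(res^2)),
         iterations = iter),
    class = "form_params"
  )
}

#' @export
print.form_params <- function(x, ...) {
  if (x$form_kind == "plane") {
    cat(sprintf("<plane form: z = %.4g + %.4g x + %.4g y, rms %.4g um>\n",
                x$plane[1], x$plane[2], x$plane[3], x$fit_rms))
  } else {
    cat(sprintf(
      "<sphere form: center (%.4g, %.4g, %.4g), radius %.6g um, rms %.4g um>\n",
      x$center[1], x$center[2], x$center[3], x$radius, x$fit_rms))
  }
  invisible(x)
}

#' Evaluate a fitted form at (x, y)
#'
#' @param form A `form_params` object from [fit_form()].
#' @param x,y Coordinates in um.
#' @return Form heights in um. For a sphere, the branch (upper or lower
#'   hemisphere) chosen during fitting is used; beyond the sphere's lateral
#'   extent the height saturates at the equator.
#' @export
form_height <- function(form, x, y) {
  stopifnot(inherits(form, "form_params"))
  if (form$form_kind == "plane") {
    form$plane[1] + form$plane[2] * x + form$plane[3] * y
  } else {
    rho2 <- (x - form$center[1])^2 + (y - form$center[2])^2
    form$center[3] + form$branch * sqrt(pmax(form$radius^2 - rho2, 0))
  }
}

#' Subtract a fitted form from a DEM
#'
#' Each non-missing cell becomes the residual `z - form(x, y)`; missing cells
#' stay missing. A plane-removed DEM has zero mean residual to numerical
#' precision.
#'
#' @param d A [dem()].
#' @param form A `form_params` from [fit_form()] on a compatible frame.
#' @return The leveled [dem()].
#' @export
remove_form <- function(d, form) {
  stopifnot(inherits(d, "dem"), inherits(form, "form_params"))
  xs <- dem_x(d); ys <- dem_y(d)
  F <- outer(ys, xs, function(yy, xx) form_height(form, xx, yy))
  d$z <- d$z - F
  d$provenance <- c(d$provenance, sprintf("remove_form(%s)", form$form_kind))
  d
}

#' Quantify how form-removal leveling biases depth measurements
#'
#' Pairs raw and leveled depth measurements by `feature_id` and reports
#' per-feature and summary differences. Sign conventions follow the direction
#' of the bias on real crowns: for defects the percent difference is
#' `100 * (raw - leveled) / raw` (how much *shallower* the leveled value is);
#' for perikymata it is `100 * (leveled - raw) / raw` (how much *deeper*
#' leveling makes them appear). Absolute differences are reported in um.
#'
#' @param raw,leveled Data frames with `feature_id`, `feature_kind` and
#'   `depth_um` (one row per feature; aggregate replicates first).
#' @return A `leveling_report`: `per_feature` tibble and `summary` tibble
#'   (mean and range of percent and absolute differences by feature kind).
#' @export
leveling_bias <- function(raw, leveled) {
  raw <- tibble::as_tibble(raw); leveled <- tibble::as_tibble(leveled)
  need <- c("feature_id", "feature_kind", "depth_um")
  if (!all(need %in% names(raw)) || !all(need %in% names(leveled))) {
    ed_stop("inputs need feature_id, feature_kind, depth_um", "ed_bad_input")
  }
  if (!setequal(raw$feature_id, leveled$feature_id)) {
    ed_stop("unmatched feature_ids between raw and leveled inputs",
            "ed_pairing")
  }
  m <- dplyr::inner_join(
    dplyr::select(raw, "feature_id", "feature_kind", raw_depth = "depth_um"),
    dplyr::select(leveled, "feature_id", leveled_depth = "depth_um"),
    by = "feature_id"
  )
  m$absolute_difference <- abs(m$raw_depth - m$leveled_depth)
  m$percent_difference <- ifelse(
    m$feature_kind == "perikyma",
    100 * (m$leveled_depth - m$raw_depth) / m$raw_depth,
    100 * (m$raw_depth - m$leveled_depth) / m$raw_depth
  )
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
  structure(list(per_feature = m, summary = s), class = "leveling_report")
}

#' @export
print.leveling_report <- function(x, ...) {
  cat("<leveling_report>\n")
  print(x$summary)
  invisible(x)
}

#' Write a leveling report (CSV per-feature table + JSON summary)
#' @param report A `leveling_report`.
#' @param path CSV path; summary goes to `paste0(path, ".json")`.
#' @export
write_leveling_report <- function(report, path) {
  stopifnot(inherits(report, "leveling_report"))
  readr::write_csv(report$per_feature, path)
  jsonlite::write_json(report$summary, paste0(path, ".json"), digits = NA,
                       dataframe = "rows")
  invisible(path)
}
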