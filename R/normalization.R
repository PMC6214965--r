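#' Isotropically scale a spine to unit height
#'
#' Divides all three coordinates by the spinal height (the vertical chord
#' z(T1) - z(L5)) and translates z so that z(L5) = 0. The single isotropic
#' factor preserves shape: every inter-landmark ratio is unchanged. x and y
#' are scaled but not re-centred, so lateral and sagittal offsets remain part
#' of the shape signal.
#'
#' @param spine A `centroid_spine` with z(T1) > z(L5).
#' @return A `scaled_spine` (same structure, dimensionless coordinates,
#'   z running from 1 at T1 to 0 at L5).
#' @export
scale_isotropic <- function(spine) {
  validate_spine(spine)
  z <- spine$coords[, "z"]
  h <- z["T1"] - z["L5"]
  if (!is.finite(h) || h <= 0)
    stop("non-positive spinal height for patient '", spine$patient_id, "'")
  coords <- spine$coords / h
  coords[, "z"] <- coords[, "z"] - coords["L5", "z"]
  out <- spine
  out$coords <- coords
  class(out) <- c("scaled_spine", "centroid_spine")
  out
}

#' Build the control z-template
#'
#' Averages the scaled z-levels of non-scoliotic control spines per vertebra.
#' The resulting 17 reference levels (1 at T1 down to 0 at L5) define the
#' common vertical grid at which every patient curve is resampled, removing
#' between-subject variability in the z direction.
#'
#' @param controls Non-empty list of `scaled_spine` objects
#'   (see [scale_isotropic()]).
#' @return Object of class `control_template`: named numeric vector of 17
#'   strictly decreasing z-levels with endpoints exactly 1 and 0.
#' @export
build_control_template <- function(controls) {
  if (inherits(controls, "centroid_spine")) controls <- list(controls)
  if (length(controls) == 0L) stop("need at least one control spine")
  ok <- vapply(controls, inherits, logical(1L), what = "scaled_spine")
  if (!all(ok)) stop("controls must be scaled spines (see scale_isotropic)")
  zmat <- vapply(controls, function(s) s$coords[, "z"], numeric(17L))
  z <- rowMeans(zmat)
  # endpoints are means of exact 1s and 0s; pin them exactly
  z["T1"] <- 1
  z["L5"] <- 0
  if (any(diff(z) >= 0)) stop("mean control z-levels are not strictly decreasing")
  structure(z, class = "control_template")
}

#' @export
print.control_template <- function(x, ...) {
  cat("<control_template> 17 z-levels, T1 = 1 .. L5 = 0\n")
  print(round(unclass(x), 4))
  invisible(x)
}

#' Resample a scaled spine at the template z-levels
#'
#' Evaluates x(z) and y(z) by piecewise-linear interpolation along the
#' spine's own centroids at the 17 template levels, yielding (x, y)
#' coordinates on a common vertical grid for all patients. If the spine's
#' z-levels coincide with the template the curve is returned unchanged.
#'
#' @param spine A `scaled_spine`.
#' @param template A `control_template`.
#' @return Object of class `normalized_curve`: list with `patient_id`,
#'   `timepoint`, `z` (template levels), `x`, `y`, and `features`, the
#'   34-element clustering vector `c(x, y)`.
#' @export
resample_at_template <- function(spine, template) {
  if (!inherits(spine, "scaled_spine"))
    stop("spine must be a scaled_spine (see scale_isotropic)")
  if (!inherits(template, "control_template")) stop("not a control_template")
  z <- spine$coords[, "z"]
  if (any(diff(z) >= 0)) stop("spine z not strictly decreasing")
  tz <- unclass(template)
  zi <- rev(z)  # approx() wants increasing abscissae
  x <- approx(zi, rev(spine$coords[, "x"]), xout = tz, method = "linear",
              ties = "ordered")$y
  y <- approx(zi, rev(spine$coords[, "y"]), xout = tz, method = "linear",
              ties = "ordered")$y
  feat <- c(x, y)
  if (!all(is.finite(feat))) stop("non-finite resampled coordinates")
  names(x) <- names(y) <- .VERTEBRAE
  structure(list(patient_id = spine$patient_id, timepoint = spine$timepoint,
                 z = tz, x = x, y = y, features = unname(feat)),
            class = "normalized_curve")
}

#' @export
print.normalized_curve <- function(x, ...) {
  cat(sprintf("<normalized_curve> patient %s, timepoint %s (34 features)\n",
              x$patient_id, x$timepoint))
  invisible(x)
}

#' Stack normalized curves into a feature matrix
#'
#' @param curves List of `normalized_curve` objects.
#' @return Numeric n x 34 matrix, one row per curve (x at the 17 template
#'   levels, then y); rownames are patient ids.
#' @export
curve_features <- function(curves) {
  if (inherits(curves, "normalized_curve")) curves <- list(curves)
  m <- t(vapply(curves, function(cu) cu$features, numeric(34L)))
  rownames(m) <- vapply(curves, function(cu) cu$patient_id, character(1L))
  m
}

#' Normalize a set of spines against a control template
#'
#' Convenience wrapper: isotropic scaling followed by template resampling
#' for every spine in a list.
#'
#' @param spines List of `centroid_spine` objects (unscaled, in mm).
#' @param template A `control_template`.
#' @return List of `normalized_curve` objects.
#' @export
normalize_spines <- function(spines, template) {
  if (inherits(spines, "centroid_spine")) spines <- list(spines)
  lapply(spines, function(s) resample_at_template(scale_isotropic(s), template))
}
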