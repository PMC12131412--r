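#' Fit a coordinate normalizer
#'
#' The network regresses on unit-interval targets, so reference coordinates
#' are rescaled per axis by min-max normalization. In Cartesian mode the
#' min/max of each raw axis are stored. In polar mode (useful for roughly
#' circular tissues) 2D points are first converted to (radius, angle) about
#' the centroid of the fitted points - angle in radians in (-pi, pi] - and
#' min-max parameters are stored for the radius and angle axes.
#'
#' @param coords numeric matrix (observations x 2 or 3).
#' @param system `"cartesian"` or `"polar"` (polar requires 2D).
#' @return A `coord_normalizer` with fields `system`, `min`, `max`, and
#'   `polar_center` when polar.
#' @export
fit_coord_normalizer <- function(coords, system = c("cartesian", "polar")) {
  system <- match.arg(system)
  coords <- as.matrix(coords)
  if (nrow(coords) < 2L) {
    stop_stmap("stmap_validation_error",
               "need at least 2 observations to fit a normalizer")
  }
  center <- NULL
  if (system == "polar") {
    if (ncol(coords) != 2L) {
      stop_stmap("stmap_validation_error", "polar mode requires 2D coordinates")
    }
    center <- colMeans(coords)
    coords <- to_polar(coords, center)
  }
  mins <- apply(coords, 2, min)
  maxs <- apply(coords, 2, max)
  if (any(maxs - mins <= 0)) {
    ax <- which(maxs - mins <= 0)[1]
    stop_stmap("stmap_degenerate_geometry_error",
               "axis %d has zero range (min == max == %g)", ax, mins[ax])
  }
  structure(list(system = system, min = mins, max = maxs,
                 polar_center = center),
            class = "coord_normalizer")
}

to_polar <- function(coords, center) {
  dx <- coords[, 1] - center[1]
  dy <- coords[, 2] - center[2]
  cbind(radius = sqrt(dx^2 + dy^2), angle = atan2(dy, dx))
}

from_polar <- function(polar, center) {
  cbind(x = center[1] + polar[, 1] * cos(polar[, 2]),
        y = center[2] + polar[, 1] * sin(polar[, 2]))
}

check_normalizer <- function(normalizer, coords) {
  if (!inherits(normalizer, "coord_normalizer")) {
    stop_stmap("stmap_validation_error", "not a coord_normalizer")
  }
  if (ncol(coords) != length(normalizer$min)) {
    stop_stmap("stmap_validation_error",
               "coordinate dimension %d does not match normalizer dimension %d",
               ncol(coords), length(normalizer$min))
  }
}

#' Map raw coordinates to the unit interval
#'
#' Applies the fitted min-max map (after polar conversion when the
#' normalizer is polar). Points inside the fitted range land in `[0,1]^d`;
#' points outside are mapped linearly with no clipping.
#'
#' @param coords numeric matrix in raw units.
#' @param normalizer a fitted `coord_normalizer`.
#' @return Matrix of normalized coordinates.
#' @export
normalize_coords <- function(coords, normalizer) {
  coords <- as.matrix(coords)
  if (normalizer$system == "polar" && ncol(coords) == 2L) {
    coords <- to_polar(coords, normalizer$polar_center)
  }
  check_normalizer(normalizer, coords)
  sweep(sweep(coords, 2, normalizer$min, "-"), 2,
        normalizer$max - normalizer$min, "/")
}

#' Map unit-interval coordinates back to raw units
#'
#' Inverse of [normalize_coords()]: undoes the min-max map and, for a polar
#' normalizer, converts (radius, angle) back to Cartesian about the stored
#' center.
#'
#' @param unit_coords numeric matrix of normalized coordinates.
#' @param normalizer a fitted `coord_normalizer`.
#' @return Matrix of coordinates in raw units.
#' @export
denormalize_coords <- function(unit_coords, normalizer) {
  unit_coords <- as.matrix(unit_coords)
  check_normalizer(normalizer, unit_coords)
  raw <- sweep(sweep(unit_coords, 2, normalizer$max - normalizer$min, "*"),
               2, normalizer$min, "+")
  if (normalizer$system == "polar") {
    raw <- from_polar(raw, normalizer$polar_center)
  }
  raw
}

#' @export
print.coord_normalizer <- function(x, ...) {
  cat(sprintf("coord_normalizer (%s): min = [%s], max = [%s]\n", x$system,
              paste(signif(x$min, 4), collapse = ", "),
              paste(signif(x$max, 4), collapse = ", ")))
  invisible(x)
}
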