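#' Construct a polyline
#'
#' A polyline is an ordered sequence of 2-D sub-pixel points representing a
#' traced fiber centerline. Coordinates follow the package-wide convention:
#' `(x, y) = (column, row)`, 0-based, with pixel centers at integer
#' coordinates.
#'
#' @param x,y Numeric vectors of equal length (>= 2) with finite coordinates.
#' @param pixel_size_um Physical size of one pixel in micrometers (default 1).
#' @return An object of class `polyline`: a list with a two-column `points`
#'   matrix (columns `x`, `y`) and the `pixel_size_um` scalar.
#' @examples
#' p <- polyline(c(0, 3), c(0, 4))
#' arc_length(p)
#' @export
polyline <- function(x, y, pixel_size_um = 1.0) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("a polyline needs at least 2 points")
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("polyline coordinates must be finite")
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0) {
    stop("pixel_size_um must be a positive finite scalar")
  }
  dup <- which(diff(x) == 0 & diff(y) == 0)
  if (length(dup) > 0L) {
    # consecutive duplicates carry no geometry; drop them
    keep <- setdiff(seq_along(x), dup + 1L)
    x <- x[keep]
    y <- y[keep]
    if (length(x) < 2L) stop("degenerate polyline: all points coincide")
  }
  structure(
    list(points = cbind(x = x, y = y), pixel_size_um = pixel_size_um),
    class = "polyline"
  )
}

#' @exportS3Method base::print
print.polyline <- function(x, ...) {
  n <- nrow(x$points)
  cat(sprintf(
    "polyline: %d points, arc %.3f, chord %.3f (pixel size %g um)\n",
    n, arc_length(x), chord_length(x), x$pixel_size_um
  ))
  invisible(x)
}

stopifnot_polyline <- function(p) {
  if (!inherits(p, "polyline")) stop("expected a polyline object")
}

#' Arc length of a polyline
#'
#' Sum of Euclidean segment lengths, multiplied by the pixel size, i.e. the
#' end-to-end length measured along the curve.
#'
#' @param p A [polyline].
#' @return Length in the units of `pixel_size_um` (micrometers when the pixel
#'   size is physical, pixels when it is 1).
#' @export
arc_length <- function(p) {
  stopifnot_polyline(p)
  d <- diff(p$points)
  sum(sqrt(d[, 1]^2 + d[, 2]^2)) * p$pixel_size_um
}

#' Chord length of a polyline
#'
#' Euclidean distance between the first and last points (the "linear
#' distance" of a traced fiber), multiplied by the pixel size.
#'
#' @inheritParams arc_length
#' @return Length in the same units as [arc_length()].
#' @export
chord_length <- function(p) {
  stopifnot_polyline(p)
  a <- p$points[1L, ]
  b <- p$points[nrow(p$points), ]
  sqrt(sum((b - a)^2)) * p$pixel_size_um
}

#' Resample a polyline at uniform arc-length spacing
#'
#' Produces a new polyline whose points are spaced (approximately)
#' `spacing_px` apart along the original curve. The first and last points are
#' preserved exactly.
#'
#' @inheritParams arc_length
#' @param spacing_px Target spacing in pixels (> 0).
#' @return A [polyline].
#' @export
resample_polyline <- function(p, spacing_px) {
  stopifnot_polyline(p)
  if (!is.numeric(spacing_px) || spacing_px <= 0) {
    stop("spacing_px must be > 0")
  }
  pts <- p$points
  seg <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total == 0) stop("degenerate polyline: zero arc length")
  n_out <- max(2L, ceiling(total / spacing_px) + 1L)
  t_out <- seq(0, total, length.out = n_out)
  x <- stats::approx(s, pts[, 1], xout = t_out, ties = "ordered")$y
  y <- stats::approx(s, pts[, 2], xout = t_out, ties = "ordered")$y
  # endpoints exact (approx can introduce rounding at the boundary)
  x[1] <- pts[1, 1]; y[1] <- pts[1, 2]
  x[n_out] <- pts[nrow(pts), 1]; y[n_out] <- pts[nrow(pts), 2]
  polyline(x, y, pixel_size_um = p$pixel_size_um)
}

#' Fiber waviness (arc-to-chord ratio)
#'
#' Waviness of a traced fiber is defined as the length measured along the
#' curve divided by the straight-line (chord) distance between its endpoints.
#' The ratio is dimensionless and >= 1, with 1 meaning a perfectly straight
#' fiber.
#'
#' @inheritParams arc_length
#' @param chord_eps Minimum admissible chord length in pixels; traces whose
#'   endpoints (nearly) coincide have an undefined ratio (default 1 px).
#' @return Dimensionless waviness ratio (>= 1 up to numerical tolerance).
#' @export
fiber_waviness <- function(p, chord_eps = 1.0) {
  stopifnot_polyline(p)
  ch <- chord_length(p) / p$pixel_size_um  # compare in pixels
  if (ch <= chord_eps) {
    stop("degenerate fiber: chord length <= ", chord_eps, " px")
  }
  arc_length(p) / chord_length(p)
}

#' Apply a rigid transform to a polyline
#'
#' Rotates by `angle_deg` (counter-clockwise about the origin in the x/y
#' convention) and then translates. Used by the generator to place fibers and
#' by tests of rotation invariance.
#'
#' @inheritParams arc_length
#' @param angle_deg Rotation angle in degrees.
#' @param dx,dy Translation in pixels.
#' @return A [polyline].
#' @export
transform_polyline <- function(p, angle_deg = 0, dx = 0, dy = 0) {
  stopifnot_polyline(p)
  th <- angle_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
  pts <- p$points %*% t(R)
  polyline(pts[, 1] + dx, pts[, 2] + dy, pixel_size_um = p$pixel_size_um)
}
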