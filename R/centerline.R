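# Sinusoidal centerline family with exact arc/chord control.
#
# A fiber centerline is a single-frequency sinusoid over a straight chord:
#   y(x) = A * sin(k x + phi),  k = 2 pi n_periods / L,  x in [0, L].
# With an integer number of periods both endpoints share the same y, so the
# chord length is exactly L and the arc/chord ratio is independent of the
# phase. The amplitude A is solved by bisection so that the ratio hits a
# requested target.

# composite-Simpson arc length of the continuous sinusoid (per unit chord)
sinusoid_arc_ratio <- function(amplitude, k, length_px, n_nodes = 2001L) {
  if (n_nodes %% 2L == 0L) n_nodes <- n_nodes + 1L
  x <- seq(0, length_px, length.out = n_nodes)
  f <- sqrt(1 + (amplitude * k * cos(k * x))^2)
  h <- length_px / (n_nodes - 1L)
  w <- rep(c(2, 4), length.out = n_nodes)
  w[1] <- 1
  w[n_nodes] <- 1
  (h / 3) * sum(w * f) / length_px
}

solve_sinusoid_amplitude <- function(waviness_target, k, length_px,
                                     tol = 1e-6) {
  if (waviness_target == 1) return(0)
  lo <- 0
  hi <- 1 / k  # slope amplitude A*k = 1 gives ratio ~1.216; expand if needed
  while (sinusoid_arc_ratio(hi, k, length_px) < waviness_target) hi <- hi * 2
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (sinusoid_arc_ratio(mid, k, length_px) < waviness_target) {
      lo <- mid
    } else {
      hi <- mid
    }
    if (hi - lo < tol * max(1, hi)) break
  }
  (lo + hi) / 2
}

#' Generate a sinusoidal fiber centerline with a prescribed waviness
#'
#' Builds a densely sampled centerline from the package's sinusoid family
#' whose arc-to-chord ratio equals `waviness_target` to within 1e-4. The
#' amplitude is found by bisection against a numerical arc-length quadrature
#' of the continuous curve. A straight segment is returned for a target of
#' exactly 1.
#'
#' @param waviness_target Desired arc/chord ratio (>= 1).
#' @param length_px Chord length in pixels (> 0).
#' @param orientation_deg Chord orientation in degrees (0 = along x).
#' @param phase Sinusoid phase in radians; drawn uniformly from `[0, 2*pi)`
#'   using the current RNG state when `NULL`.
#' @param n_periods Integer number of full sinusoid periods along the chord
#'   (default 3). An integer count keeps the chord independent of the phase.
#' @param spacing_px Sample spacing along the curve (<= 1 px; default 0.5).
#' @return A [polyline] starting at the origin, rotated to
#'   `orientation_deg`.
#' @export
make_centerline <- function(waviness_target, length_px, orientation_deg = 0,
                            phase = NULL, n_periods = 3L, spacing_px = 0.5) {
  if (!is.numeric(waviness_target) || waviness_target < 1) {
    stop("waviness_target must be >= 1 (arc length never undercuts the chord)")
  }
  if (!is.numeric(length_px) || length_px <= 0) stop("length_px must be > 0")
  if (spacing_px <= 0 || spacing_px > 1) stop("spacing_px must be in (0, 1]")
  if (is.null(phase)) phase <- stats::runif(1, 0, 2 * pi)
  k <- 2 * pi * n_periods / length_px
  A <- solve_sinusoid_amplitude(waviness_target, k, length_px)
  # sample so that spacing along the *arc* stays <= spacing_px
  n_pts <- max(2L, ceiling(length_px * waviness_target / spacing_px) + 1L)
  x <- seq(0, length_px, length.out = n_pts)
  y <- A * sin(k * x + phase) - A * sin(phase)  # start at the origin
  p <- polyline(x, y)
  if (orientation_deg != 0) p <- transform_polyline(p, orientation_deg)
  p
}

#' Fiber specification (ground truth for one rendered fiber)
#'
#' @param centerline A [polyline] giving the true centerline.
#' @param width Fiber width in pixels (flat-top cross profile).
#' @param peak_intensity Intensity added along the fiber, in counts.
#' @param true_waviness Optional; recomputed from the centerline when `NULL`
#'   and checked against it (to 1e-6) otherwise.
#' @return An object of class `fiber_spec`.
#' @export
fiber_spec <- function(centerline, width, peak_intensity,
                       true_waviness = NULL) {
  stopifnot_polyline(centerline)
  if (width <= 0) stop("width must be > 0")
  if (peak_intensity < 0) stop("peak_intensity must be >= 0")
  w <- fiber_waviness(centerline)
  if (!is.null(true_waviness) && abs(true_waviness - w) > 1e-6) {
    stop("true_waviness inconsistent with centerline arc/chord ratio")
  }
  structure(
    list(centerline = centerline, width = width,
         peak_intensity = peak_intensity, true_waviness = w),
    class = "fiber_spec"
  )
}
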