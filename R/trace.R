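# Seeded automated ridge tracing of bright curvilinear fibers.
#
# Replaces manual mouse tracing with a deterministic procedure: from a seed
# point on a fiber, follow the intensity ridge in both directions, advancing
# a fixed step and re-centering on the intensity-weighted centroid along the
# local normal at every step. Sub-pixel intensities come from bilinear
# interpolation; all decisions are deterministic, so the same image, seed
# point and parameters always yield the same polyline.

#' Tracing parameters
#'
#' @param fiber_width_px Estimate of the fiber width in pixels; sets the
#'   default centering window.
#' @param step_px Step length along the fiber per iteration (default 2).
#' @param normal_halfwidth_px Half-width of the centering window along the
#'   normal (default 1.5 x the fiber width estimate).
#' @param stop_intensity_fraction Stop when the local ridge intensity falls
#'   below this fraction of the seed intensity (default 0.5, in (0, 1)).
#' @param max_turn_deg Maximum direction change per step in degrees
#'   (default 30); larger turns terminate the trace (straightest-continuation
#'   rule at fiber crossings).
#' @param max_steps Step cap per direction (default 2000).
#' @return A list of class `trace_params`.
#' @export
trace_params <- function(fiber_width_px = 10, step_px = 2,
                         normal_halfwidth_px = 1.5 * fiber_width_px,
                         stop_intensity_fraction = 0.5, max_turn_deg = 30,
                         max_steps = 2000L) {
  if (step_px <= 0) stop("step_px must be > 0")
  if (stop_intensity_fraction <= 0 || stop_intensity_fraction >= 1) {
    stop("stop_intensity_fraction must be in (0, 1)")
  }
  if (normal_halfwidth_px <= 0) stop("normal_halfwidth_px must be > 0")
  structure(
    list(fiber_width_px = fiber_width_px, step_px = step_px,
         normal_halfwidth_px = normal_halfwidth_px,
         stop_intensity_fraction = stop_intensity_fraction,
         max_turn_deg = max_turn_deg, max_steps = as.integer(max_steps)),
    class = "trace_params"
  )
}

# bilinear interpolation at 0-based (x, y); returns NA outside the grid
bilinear <- function(pixels, x, y) {
  n_row <- nrow(pixels)
  n_col <- ncol(pixels)
  x0 <- floor(x); y0 <- floor(y)
  # clamp the upper edge so points exactly on the last row/column interpolate
  x0 <- pmin(x0, n_col - 2); y0 <- pmin(y0, n_row - 2)
  out <- rep(NA_real_, length(x))
  inb <- x >= 0 & x <= n_col - 1 & y >= 0 & y <= n_row - 1
  if (!any(inb)) return(out)
  xi <- x0[inb]; yi <- y0[inb]
  fx <- x[inb] - xi; fy <- y[inb] - yi
  i00 <- xi * n_row + yi + 1
  v00 <- pixels[i00]; v10 <- pixels[i00 + n_row]
  v01 <- pixels[i00 + 1]; v11 <- pixels[i00 + n_row + 1]
  out[inb] <- v00 * (1 - fx) * (1 - fy) + v10 * fx * (1 - fy) +
    v01 * (1 - fx) * fy + v11 * fx * fy
  out
}

# dominant local orientation: principal axis of the thresholded,
# intensity-weighted second-moment matrix in a square window
local_orientation <- function(pixels, x, y, radius, threshold) {
  g <- expand.grid(dx = seq(-radius, radius, by = 1),
                   dy = seq(-radius, radius, by = 1))
  v <- bilinear(pixels, x + g$dx, y + g$dy)
  w <- pmax(v - threshold, 0)
  w[is.na(w)] <- 0
  if (sum(w) == 0) return(c(1, 0))  # tie: image x-axis
  mx <- sum(w * g$dx) / sum(w)
  my <- sum(w * g$dy) / sum(w)
  sxx <- sum(w * (g$dx - mx)^2)
  syy <- sum(w * (g$dy - my)^2)
  sxy <- sum(w * (g$dx - mx) * (g$dy - my))
  e <- eigen(matrix(c(sxx, sxy, sxy, syy), 2, 2), symmetric = TRUE)
  dir <- e$vectors[, 1]
  if (abs(dir[1]) < 1e-12 && abs(dir[2]) < 1e-12) return(c(1, 0))
  dir / sqrt(sum(dir^2))
}

# re-center a point on the intensity-weighted centroid along the normal
recenter <- function(pixels, pt, dir, halfwidth, threshold) {
  nrm <- c(-dir[2], dir[1])
  t_off <- seq(-halfwidth, halfwidth, by = 0.5)
  v <- bilinear(pixels, pt[1] + nrm[1] * t_off, pt[2] + nrm[2] * t_off)
  w <- pmax(v - threshold, 0)
  w[is.na(w)] <- 0
  if (sum(w) == 0) return(NULL)
  pt + nrm * sum(w * t_off) / sum(w)
}

trace_one_direction <- function(pixels, start, dir, params, threshold) {
  pts <- list()
  pos <- start
  cos_max <- cos(params$max_turn_deg * pi / 180)
  n_row <- nrow(pixels); n_col <- ncol(pixels)
  # The discrete tube center oscillates around the continuous ridge by up
  # to ~0.5 px (rasterization sawtooth), so single-step directions carry
  # ~10 degrees of jitter. March and gate on a direction estimated over a
  # few-step baseline instead.
  baseline <- 3L
  for (step in seq_len(params$max_steps)) {
    cand <- pos + dir * params$step_px
    if (cand[1] < 1 || cand[1] > n_col - 2 ||
        cand[2] < 1 || cand[2] > n_row - 2) break  # image border
    # re-center first: on curved ridges the dead-reckoned candidate can sit
    # off the crest even though the ridge continues
    newpos <- recenter(pixels, cand, dir, params$normal_halfwidth_px,
                       threshold)
    if (is.null(newpos)) break
    v <- bilinear(pixels, newpos[1], newpos[2])
    if (is.na(v) || v < threshold) break            # intensity stop
    if (sum((newpos - pos)^2) < 1e-18) break
    ref <- if (length(pts) >= baseline) {
      pts[[length(pts) - baseline + 1L]]
    } else {
      start
    }
    bd <- newpos - ref
    bd <- bd / sqrt(sum(bd^2))
    # gate on the rotation of the baseline direction; it engages once the
    # baseline fills (the seed direction is only an orientation estimate)
    if (step > baseline && sum(bd * dir) < cos_max) break  # turn limit
    pts[[length(pts) + 1L]] <- newpos
    pos <- newpos
    dir <- bd
  }
  pts
}

#' Trace a fiber centerline from a seed point
#'
#' Bidirectional ridge following from `seed_point`: the local dominant
#' orientation seeds the initial direction, then each step advances
#' `step_px` and re-centers on the intensity-weighted centroid along the
#' normal. The trace terminates at the image border, when the ridge
#' intensity drops below `stop_intensity_fraction` of the seed intensity,
#' when the direction would turn more than `max_turn_deg`, or at
#' `max_steps`.
#'
#' @param img An [image16].
#' @param seed_point Numeric `c(x, y)`, 0-based, inside the image, on a
#'   fiber (intensity well above background).
#' @param params A [trace_params].
#' @return A [polyline] (inherits the image's pixel size).
#' @export
trace_fiber <- function(img, seed_point, params = trace_params()) {
  stopifnot_image16(img)
  if (!inherits(params, "trace_params")) stop("params must be trace_params")
  pixels <- img$pixels
  x <- seed_point[1]; y <- seed_point[2]
  if (x < 0 || x > ncol(pixels) - 1 || y < 0 || y > nrow(pixels) - 1) {
    stop("seed point outside the image")
  }
  seed_int <- bilinear(pixels, x, y)
  bg <- stats::median(pixels)
  if (is.na(seed_int) || seed_int < 1.5 * bg + 1) {
    stop("seed not on a fiber: intensity ", round(seed_int, 1),
         " is not above background (~", round(bg, 1), ")")
  }
  threshold <- params$stop_intensity_fraction * seed_int
  dir0 <- local_orientation(pixels, x, y, 2 * params$fiber_width_px,
                            threshold)
  start <- recenter(pixels, c(x, y), dir0, params$normal_halfwidth_px,
                    threshold)
  if (is.null(start)) stop("seed not on a fiber: empty centering window")
  fwd <- trace_one_direction(pixels, start, dir0, params, threshold)
  # seed the backward half with the realized forward tangent when available
  bdir <- if (length(fwd) > 0L) {
    d <- fwd[[1L]] - start
    -d / sqrt(sum(d^2))
  } else {
    -dir0
  }
  bwd <- trace_one_direction(pixels, start, bdir, params, threshold)
  pts <- c(rev(bwd), list(start), fwd)
  if (length(pts) < 2L) stop("trace failed: fewer than 2 points")
  m <- do.call(rbind, pts)
  p <- polyline(m[, 1], m[, 2], pixel_size_um = img$pixel_size_um)
  # residual sub-pixel centering jitter inflates the polygonal arc length;
  # a short moving average (much shorter than any fiber undulation of
  # interest) removes it without attenuating the waviness signal
  smooth_polyline(resample_polyline(p, 1), window = 5L)
}

#' Smooth a polyline with a short moving average
#'
#' Applies a centered moving average of `window` vertices to the
#' coordinates, keeping the endpoints fixed. Intended to suppress sub-pixel
#' tracing jitter; the window should stay far below the wavelength of any
#' real undulation.
#'
#' @param p A [polyline].
#' @param window Odd window length in vertices (default 5).
#' @return A [polyline].
#' @export
smooth_polyline <- function(p, window = 5L) {
  stopifnot_polyline(p)
  if (window < 3L || window %% 2L == 0L) stop("window must be odd and >= 3")
  pts <- p$points
  n <- nrow(pts)
  if (n <= window) return(p)
  half <- (window - 1L) %/% 2L
  sm <- pts
  for (j in 1:2) {
    cs <- cumsum(c(0, pts[, j]))
    i <- (half + 1L):(n - half)
    sm[i, j] <- (cs[i + half + 1L] - cs[i - half]) / window
  }
  # taper the ends: shrinking symmetric windows keep endpoints exact
  for (i in seq_len(half)) {
    k <- i - 1L
    if (k >= 1L) {
      sm[i, ] <- colMeans(pts[(i - k):(i + k), , drop = FALSE])
      sm[n - i + 1L, ] <- colMeans(pts[(n - i + 1L - k):(n - i + 1L + k),
                                       , drop = FALSE])
    }
  }
  polyline(sm[, 1], sm[, 2], pixel_size_um = p$pixel_size_um)
}

#' Pick trace seed points from an image without ground truth
#'
#' For real micrographs (no generator manifest) seeds are chosen
#' deterministically: image positions on a coarse grid are ranked by local
#' intensity and the top `n` are taken greedily under a minimum-separation
#' constraint.
#'
#' @param img An [image16].
#' @param n Number of seeds (default 10).
#' @param grid_step Grid spacing in pixels (default 16).
#' @param min_separation Minimum distance between accepted seeds (default
#'   50 px).
#' @param margin Border margin excluded from seeding (default 20 px).
#' @return Matrix with columns `x`, `y` (0-based), up to `n` rows.
#' @export
pick_seed_points <- function(img, n = 10L, grid_step = 16L,
                             min_separation = 50, margin = 20L) {
  stopifnot_image16(img)
  px <- img$pixels
  xs <- seq(margin, ncol(px) - 1 - margin, by = grid_step)
  ys <- seq(margin, nrow(px) - 1 - margin, by = grid_step)
  g <- expand.grid(x = xs, y = ys)
  g$v <- px[cbind(g$y + 1, g$x + 1)]
  g <- g[order(-g$v, g$x, g$y), ]
  sel <- matrix(numeric(0), 0, 2, dimnames = list(NULL, c("x", "y")))
  for (i in seq_len(nrow(g))) {
    p <- c(g$x[i], g$y[i])
    if (nrow(sel) == 0 ||
        min(sqrt((sel[, 1] - p[1])^2 + (sel[, 2] - p[2])^2)) >=
          min_separation) {
      sel <- rbind(sel, p)
      if (nrow(sel) >= n) break
    }
  }
  rownames(sel) <- NULL
  sel
}
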