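# Rasterization and rendering of synthetic SHG-like fiber images.
#
# A fiber is painted as a flat-top tube: pixels within width/2 of the
# (densely sampled) centerline receive the fiber's peak intensity
# additively, with a one-pixel linear edge rolloff standing in for pixel
# area coverage / diffraction blur (it also preserves the tube's sub-pixel
# position for the tracer). The tube is the union of discs centered on
# centerline samples, giving rounded end caps.

# Rasterize one fiber tube with a 1-px anti-aliased edge. Returns 1-based
# column-major image indices and per-pixel weights in [0, 1]: weight 1
# strictly inside the tube (distance to the centerline <= width/2 - 1/2),
# rolling off linearly to 0 over one pixel, approximating pixel-area
# coverage the way a diffraction-blurred micrograph edge behaves.
rasterize_fiber <- function(centerline, width, n_row, n_col) {
  r <- width / 2
  # disc-union scallop depth is spacing^2/(8r): <= 0.1 px at spacing
  # sqrt(0.8 r), well under the 1-px edge rolloff
  spacing <- max(0.25, min(2, sqrt(0.8 * r)))
  pts <- resample_polyline(centerline, spacing)$points
  sx <- pts[, 1]
  sy <- pts[, 2]
  r_out <- r + 0.5
  rad <- ceiling(r_out + 0.8)
  off <- expand.grid(dx = -rad:rad, dy = -rad:rad)
  keep_off <- off$dx^2 + off$dy^2 <= (r_out + 0.8)^2
  odx <- off$dx[keep_off]
  ody <- off$dy[keep_off]
  rx <- round(sx)
  ry <- round(sy)
  fx <- sx - rx
  fy <- sy - ry
  n <- length(sx)
  m <- length(odx)
  # candidate pixel (rx + odx, ry + ody); exact distance to the sample point
  DX <- matrix(odx, n, m, byrow = TRUE) - fx
  DY <- matrix(ody, n, m, byrow = TRUE) - fy
  D2 <- DX * DX + DY * DY
  hit <- which(D2 <= r_out * r_out)
  px <- matrix(rx, n, m)[hit] + matrix(odx, n, m, byrow = TRUE)[hit]
  py <- matrix(ry, n, m)[hit] + matrix(ody, n, m, byrow = TRUE)[hit]
  d <- sqrt(D2[hit])
  # per-pixel minimum distance to the sample set: write distances in
  # decreasing order so the smallest lands last
  bx0 <- min(px); by0 <- min(py)
  h <- max(py) - by0 + 1L
  lidx <- (px - bx0) * h + (py - by0) + 1L
  dmin <- rep(NA_real_, (max(px) - bx0 + 1L) * h)
  o <- order(d, decreasing = TRUE)
  dmin[lidx[o]] <- d[o]
  keep <- which(!is.na(dmin))
  lx <- bx0 + (keep - 1L) %/% h
  ly <- by0 + (keep - 1L) %% h
  wt <- pmin(1, r_out - dmin[keep])
  inb <- lx >= 0 & lx < n_col & ly >= 0 & ly < n_row & wt > 0
  list(index = lx[inb] * n_row + ly[inb] + 1L,  # matrix index [y+1, x+1]
       weight = wt[inb])
}

#' Noise model specification
#'
#' @param type One of `"none"`, `"gaussian"` (additive read noise) or
#'   `"poisson_gaussian"` (Poisson shot noise on the clean signal plus
#'   additive read noise). All models are zero-mean: the expected image is
#'   the clean image.
#' @param sigma Read-noise standard deviation in counts.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(type = c("gaussian", "none", "poisson_gaussian"),
                        sigma = 20) {
  type <- match.arg(type)
  if (sigma < 0) stop("sigma must be >= 0")
  structure(list(type = type, sigma = sigma), class = "noise_model")
}

apply_noise <- function(values, noise) {
  switch(noise$type,
    none = values,
    gaussian = values + stats::rnorm(length(values), 0, noise$sigma),
    poisson_gaussian =
      stats::rpois(length(values), values) +
        stats::rnorm(length(values), 0, noise$sigma)
  )
}

#' Render fibers into a synthetic SHG-like image
#'
#' Paints each fiber's flat-top tube additively onto a constant background,
#' optionally adds a uniform intensity offset (e.g. a per-animal brightness
#' intercept), applies the noise model last, and rounds/clips the result into
#' the nominal bit range.
#'
#' @param fibers List of [fiber_spec] objects.
#' @param image_size Integer `c(rows, cols)`.
#' @param background_level Background intensity in counts.
#' @param noise A [noise_model] (default none).
#' @param uniform_offset Additional uniform intensity in counts (default 0).
#' @param bit_depth Nominal bit depth (default 12).
#' @param pixel_size_um Pixel size metadata.
#' @return An [image16].
#' @export
render_image <- function(fibers, image_size = c(1024L, 1024L),
                         background_level = 500, noise = noise_model("none"),
                         uniform_offset = 0, bit_depth = 12L,
                         pixel_size_um = 1.0) {
  n_row <- as.integer(image_size[1])
  n_col <- as.integer(image_size[2])
  if (n_row <= 0 || n_col <= 0) stop("image_size must be positive")
  maxv <- 2^bit_depth - 1
  peaks <- vapply(fibers, function(f) f$peak_intensity, numeric(1))
  clean_max <- background_level + uniform_offset +
    if (length(peaks)) max(peaks) else 0
  if (clean_max > maxv) {
    stop("clean intensity ", round(clean_max, 1),
         " exceeds container max ", maxv)
  }
  if (background_level + uniform_offset < 0) {
    stop("background plus offset must be >= 0")
  }
  img <- matrix(background_level + uniform_offset, n_row, n_col)
  for (f in fibers) {
    ras <- rasterize_fiber(f$centerline, f$width, n_row, n_col)
    img[ras$index] <- img[ras$index] + f$peak_intensity * ras$weight
  }
  vals <- apply_noise(as.vector(img), noise)
  vals <- pmin(pmax(round(vals), 0), maxv)
  image16(matrix(as.integer(vals), n_row, n_col), bit_depth = bit_depth,
          pixel_size_um = pixel_size_um)
}
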