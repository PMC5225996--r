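# Shared fixtures: small rendered scenes with known ground truth.

# one centered fiber of given waviness in a square noise-free field
single_fiber_scene <- function(waviness, length_px = 450, width = 10,
                               orientation_deg = 0, phase = 0.7,
                               side = 600L, peak = 1750,
                               background = 500,
                               noise = noise_model("none")) {
  cl <- make_centerline(waviness, length_px, orientation_deg, phase = phase)
  pts <- cl$points
  cl <- polyline(pts[, 1] - mean(range(pts[, 1])) + (side - 1) / 2,
                 pts[, 2] - mean(range(pts[, 2])) + (side - 1) / 2)
  f <- fiber_spec(cl, width, peak)
  list(fiber = f,
       image = render_image(list(f), c(side, side), background,
                            noise = noise))
}

# RMS distance from trace points to a densely sampled true centerline,
# restricted to points whose nearest true vertex is interior (end overshoot
# onto the tube caps is a separate property from centering accuracy)
interior_rms <- function(trace, truth) {
  tp <- truth$points
  dd <- apply(trace$points, 1, function(p) {
    d2 <- (tp[, 1] - p[1])^2 + (tp[, 2] - p[2])^2
    c(sqrt(min(d2)), which.min(d2))
  })
  inner <- dd[2, ] > 1 & dd[2, ] < nrow(tp)
  sqrt(mean(dd[1, inner]^2))
}

# brute-force soft-edge rasterization oracle: per-pixel weight from the
# exact minimum distance to a very densely sampled centerline (independent
# of the implementation's candidate-disc bookkeeping)
brute_force_weights <- function(centerline, width, n_row, n_col) {
  pts <- resample_polyline(centerline, 0.05)$points
  r_out <- width / 2 + 0.5
  w <- matrix(0, n_row, n_col)
  xr <- floor(min(pts[, 1]) - r_out - 1):ceiling(max(pts[, 1]) + r_out + 1)
  yr <- floor(min(pts[, 2]) - r_out - 1):ceiling(max(pts[, 2]) + r_out + 1)
  for (x in xr[xr >= 0 & xr < n_col]) {
    for (y in yr[yr >= 0 & yr < n_row]) {
      d <- sqrt(min((pts[, 1] - x)^2 + (pts[, 2] - y)^2))
      w[y + 1, x + 1] <- min(1, max(0, r_out - d))
    }
  }
  w
}
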