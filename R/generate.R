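# Paired treated/control condition-set generation with known ground truth.
#
# Brightness contract: a fiber's contribution to the *image mean* is what the
# configuration specifies. After the fiber layout of an image is rasterized,
# the common peak intensity is calibrated as
#   peak = offset * n_pixels / total_fiber_pixels,
# so the clean image mean is exactly background + uniform offsets +
# fiber_intensity_offset for that arm, independent of placement randomness.
# Under the zero-mean noise models the expected treated-minus-control image
# mean therefore equals expected_mean_difference by construction.

# deterministic sub-stream seeds: fold integers into [0, 2^31 - 59)
substream_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  h <- 0
  for (v in parts) {
    h <- (h * 1000003 + (as.numeric(v) %% 2147483647)) %% 2147483589
  }
  as.integer(h)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  force(expr)
}

#' Generator configuration for a synthetic crosslinking condition
#'
#' Fully parameterizes one synthetic condition: paired treated/control
#' SHG-like images per animal, with condition-dependent fiber brightness and
#' centerline waviness, a shared per-animal brightness intercept, and a
#' zero-mean noise model. `fiber_intensity_offset_*` give each arm's fiber
#' contribution to the image mean, in counts (see the rendering contract in
#' the package vignette), so `expected_mean_difference` is their difference.
#'
#' @param name Identifier for the condition.
#' @param image_size Integer `c(rows, cols)`; default 1024 x 1024.
#' @param background_level Background intensity in counts.
#' @param fiber_intensity_offset_control,fiber_intensity_offset_treated
#'   Fiber contribution to the image mean per arm, counts.
#' @param waviness_control,waviness_treated Ground-truth arc/chord ratio per
#'   arm (>= 1).
#' @param n_fibers_per_image,fiber_width,fiber_length Fiber geometry
#'   (count, pixels, chord pixels).
#' @param fiber_separation Minimum distance between fiber centerlines in
#'   pixels, enforced by rejection sampling. The default (= `fiber_width`)
#'   keeps tubes non-overlapping; presets meant for tracing use a wider
#'   margin so the tracer's centering window never sees a neighbor.
#' @param waviness_fiber_sd Per-fiber jitter (SD) on the waviness ratio,
#'   truncated at 1; default 0.02.
#' @param difference_sd SD of the zero-mean per-animal treatment-effect
#'   variability added to the treated arm's brightness offset, in counts
#'   (default 28, emulating the between-animal spread of paired brightness
#'   differences seen in crosslinked sclera).
#' @param noise A [noise_model]; default Gaussian read noise, sigma 20.
#' @param n_rabbits Number of animals (paired eyes) per condition.
#' @param rabbit_intercept_sd SD of the per-animal shared brightness
#'   intercept, counts (default 10).
#' @param seed Integer seed; all randomness derives from it.
#' @param expected_mean_difference Optional; validated against
#'   `fiber_intensity_offset_treated - fiber_intensity_offset_control` when
#'   supplied, derived otherwise.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(name,
                             image_size = c(1024L, 1024L),
                             background_level = 500,
                             fiber_intensity_offset_control = 100,
                             fiber_intensity_offset_treated = 100,
                             waviness_control = 1.3,
                             waviness_treated = 1.3,
                             n_fibers_per_image = 30L,
                             fiber_width = 10,
                             fiber_length = 500,
                             fiber_separation = fiber_width,
                             waviness_fiber_sd = 0.02,
                             difference_sd = 28,
                             noise = noise_model("gaussian", 20),
                             n_rabbits = 10L,
                             rabbit_intercept_sd = 10,
                             seed = 1L,
                             expected_mean_difference = NULL) {
  if (waviness_control < 1 || waviness_treated < 1) {
    stop("waviness ratios must be >= 1")
  }
  if (fiber_intensity_offset_control < 0 ||
      fiber_intensity_offset_treated < 0) {
    stop("fiber intensity offsets must be >= 0")
  }
  if (n_rabbits < 2) stop("n_rabbits must be >= 2")
  if (n_fibers_per_image < 1) stop("n_fibers_per_image must be >= 1")
  if (!inherits(noise, "noise_model")) stop("noise must be a noise_model")
  derived <- fiber_intensity_offset_treated - fiber_intensity_offset_control
  if (!is.null(expected_mean_difference) &&
      abs(expected_mean_difference - derived) > 1e-9) {
    stop("expected_mean_difference must equal the treated-minus-control ",
         "fiber intensity offset (", derived, ")")
  }
  structure(
    list(name = name, image_size = as.integer(image_size),
         background_level = background_level,
         fiber_intensity_offset_control = fiber_intensity_offset_control,
         fiber_intensity_offset_treated = fiber_intensity_offset_treated,
         expected_mean_difference = derived,
         waviness_control = waviness_control,
         waviness_treated = waviness_treated,
         n_fibers_per_image = as.integer(n_fibers_per_image),
         fiber_width = fiber_width, fiber_length = fiber_length,
         fiber_separation = fiber_separation,
         waviness_fiber_sd = waviness_fiber_sd,
         difference_sd = difference_sd,
         noise = noise, n_rabbits = as.integer(n_rabbits),
         rabbit_intercept_sd = rabbit_intercept_sd,
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

# named presets calibrated so that round-trip recovery reproduces the
# published summary statistics; see the vignette for the calibration logic
preset_table <- function() {
  list(
    `cfg-int-40`  = list(fiber_intensity_offset_control = 100,
                         fiber_intensity_offset_treated = 166.3,
                         fiber_length = 200, n_fibers_per_image = 75L),
    `cfg-int-400` = list(fiber_intensity_offset_control = 100,
                         fiber_intensity_offset_treated = 461.4,
                         fiber_length = 200, n_fibers_per_image = 75L),
    `cfg-null`    = list(fiber_intensity_offset_control = 100,
                         fiber_intensity_offset_treated = 100,
                         fiber_length = 200, n_fibers_per_image = 75L),
    `cfg-wav-40`  = list(fiber_intensity_offset_control = 100,
                         fiber_intensity_offset_treated = 100,
                         difference_sd = 10,
                         waviness_control = 1.300,
                         waviness_treated = 1.189,
                         n_fibers_per_image = 10L,
                         fiber_length = 450, fiber_separation = 25),
    `cfg-wav-400` = list(fiber_intensity_offset_control = 100,
                         fiber_intensity_offset_treated = 100,
                         difference_sd = 10,
                         waviness_control = 1.300,
                         waviness_treated = 1.165,
                         n_fibers_per_image = 10L,
                         fiber_length = 450, fiber_separation = 25)
  )
}

#' Named generator presets
#'
#' Returns the [generator_config] for one of the package's named synthetic
#' conditions. `cfg-int-40` / `cfg-int-400` carry ground-truth
#' treated-minus-control mean-brightness differences of 66.3 and 361.4
#' counts; `cfg-wav-40` / `cfg-wav-400` carry control/treated waviness
#' ratios of 1.300/1.189 and 1.300/1.165 (Waviness-% 63 and 55);
#' `cfg-null` has a zero brightness difference. Any [generator_config]
#' argument can be overridden through `...` (e.g. a smaller `image_size`
#' with proportionally scaled fibers for quick runs).
#'
#' @param name Preset name.
#' @param seed Integer seed.
#' @param ... Overrides passed to [generator_config()].
#' @return A [generator_config].
#' @export
preset_config <- function(name, seed = 1L, ...) {
  tab <- preset_table()
  if (!name %in% names(tab)) {
    stop("unknown preset '", name, "'; available: ",
         paste(names(tab), collapse = ", "))
  }
  args <- tab[[name]]
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(generator_config, c(list(name = name, seed = seed), args))
}

# Place fiber centerlines as a locally aligned bundle, the way scleral
# collagen runs in parallel lamellae: all fibers of one image field share a
# random orientation and are laid in parallel "lanes" whose pitch exceeds
# the sinusoid band plus the configured separation, so non-overlap holds by
# construction (isotropic random placement cannot avoid crossings at these
# coverage fractions: long segments totalling T pixels in area A cross
# ~T^2/(pi*A) times, hundreds here).
place_fibers <- function(config, waviness) {
  n_row <- config$image_size[1]
  n_col <- config$image_size[2]
  L <- config$fiber_length
  w <- config$fiber_width
  wsd <- config$waviness_fiber_sd
  n <- config$n_fibers_per_image
  # amplitude bound over the per-fiber waviness jitter (4 sigma)
  k <- 2 * pi * 3 / L
  A_bound <- solve_sinusoid_amplitude(waviness + 4 * wsd, k, L)
  gap <- max(2, config$fiber_separation - w)
  pitch <- 2 * A_bound + w + gap
  theta <- stats::runif(1, 0, pi)
  e <- c(cos(theta), sin(theta))     # fiber axis
  nv <- c(-sin(theta), cos(theta))   # lane normal
  margin <- w / 2 + 2
  hx <- (n_col - 1) / 2 - margin
  hy <- (n_row - 1) / 2 - margin
  if (2 * min(hx, hy) < L / 1.5) stop("fiber_length too large for image_size")
  # u-interval of the centered margin square along a lane at height v:
  # |u*e_x + v*n_x| <= hx and |u*e_y + v*n_y| <= hy
  lane_interval <- function(v) {
    lo <- -Inf; hi <- Inf
    for (ax in 1:2) {
      h <- if (ax == 1) hx else hy
      a <- e[ax]; b <- v * nv[ax]
      if (abs(a) < 1e-12) {
        if (abs(b) > h) return(NULL)
      } else {
        r <- sort(c((-h - b) / a, (h - b) / a))
        lo <- max(lo, r[1]); hi <- min(hi, r[2])
      }
    }
    if (hi <= lo) NULL else c(lo, hi)
  }
  # enumerate slots (lane height v, start u) over lanes centered on v = 0
  slots <- list()
  j_max <- floor((max(hx, hy) * 1.5) / pitch) + 1L
  for (j in -j_max:j_max) {
    v <- j * pitch
    # the sinusoid band spans v +/- A_bound; both edges must stay inside
    iv_lo <- lane_interval(v - A_bound)
    iv_hi <- lane_interval(v + A_bound)
    if (is.null(iv_lo) || is.null(iv_hi)) next
    # tube end caps extend w/2 along the lane beyond the chord endpoints
    iv <- c(max(iv_lo[1], iv_hi[1]) + w / 2, min(iv_lo[2], iv_hi[2]) - w / 2)
    len <- iv[2] - iv[1]
    stride <- L + w + gap
    n_slot <- floor((len + w + gap) / stride)
    if (n_slot < 1) next
    for (m in seq_len(n_slot)) {
      slots[[length(slots) + 1L]] <- c(v, iv[1] + (m - 1) * stride)
    }
  }
  if (length(slots) < n) {
    stop("cannot place ", n, " fibers of length ", L, " in a ",
         n_row, "x", n_col, " image at pitch ", round(pitch, 1),
         " (only ", length(slots), " slots); reduce n_fibers_per_image ",
         "or fiber_length")
  }
  pick <- sample(length(slots), n)
  cx0 <- (n_col - 1) / 2
  cy0 <- (n_row - 1) / 2
  lapply(pick, function(s) {
    v <- slots[[s]][1]
    u0 <- slots[[s]][2]
    w_i <- max(1, waviness + if (wsd > 0) stats::rnorm(1, 0, wsd) else 0)
    phase <- stats::runif(1, 0, 2 * pi)
    cl <- make_centerline(w_i, L, 0, phase = phase)
    pts <- cl$points
    # center the sinusoid band vertically inside its lane
    yc <- (max(pts[, 2]) + min(pts[, 2])) / 2
    u <- u0 + pts[, 1]
    vv <- v + pts[, 2] - yc
    polyline(cx0 + u * e[1] + vv * nv[1], cy0 + u * e[2] + vv * nv[2])
  })
}

# build fiber specs and render one arm's image; peak intensity calibrated so
# the clean image mean exceeds background + uniform offsets by exactly
# `offset`
render_arm <- function(config, waviness, offset, intercept) {
  n_row <- config$image_size[1]
  n_col <- config$image_size[2]
  centerlines <- place_fibers(config, waviness)
  ras <- lapply(centerlines, rasterize_fiber, width = config$fiber_width,
                n_row = n_row, n_col = n_col)
  total_px <- sum(vapply(ras, function(r) sum(r$weight), numeric(1)))
  peak <- if (total_px > 0) offset * (n_row * n_col) / total_px else 0
  fibers <- lapply(centerlines, fiber_spec, width = config$fiber_width,
                   peak_intensity = peak)
  maxv <- 2^12 - 1
  clean_max <- config$background_level + intercept + peak
  if (clean_max > maxv) {
    stop("calibrated peak intensity ", round(peak, 1),
         " overflows the 12-bit range; lower the offset or add fibers")
  }
  img <- matrix(config$background_level + intercept, n_row, n_col)
  for (r in ras) img[r$index] <- img[r$index] + peak * r$weight
  vals <- apply_noise(as.vector(img), config$noise)
  vals <- pmin(pmax(round(vals), 0), maxv)
  list(
    image = image16(matrix(as.integer(vals), n_row, n_col), bit_depth = 12L),
    fibers = fibers
  )
}

#' Generate a paired treated/control condition set
#'
#' For each animal, draws a shared brightness intercept (the "rabbit" random
#' intercept, common to both eyes) and a zero-mean per-animal treatment
#' effect (added to the treated arm's brightness offset), then renders one
#' treated and one control image with arm-specific fiber waviness and
#' brightness, independent fiber layouts, and the configured noise model. All randomness is derived from
#' `config$seed` through per-(animal, arm) sub-streams, so identical
#' configurations reproduce bit-identical output.
#'
#' @param config A [generator_config].
#' @return An object of class `condition_set`: the config plus one entry per
#'   animal with `rabbit_id`, `intercept`, `treated`/`control` [image16]s and
#'   the ground-truth [fiber_spec] lists per arm.
#' @export
generate_condition_set <- function(config) {
  if (!inherits(config, "generator_config")) {
    stop("config must be a generator_config")
  }
  rabbits <- vector("list", config$n_rabbits)
  for (r in seq_len(config$n_rabbits)) {
    intercept <- with_seed(
      substream_seed(config$seed, r, 0),
      stats::rnorm(1, 0, config$rabbit_intercept_sd)
    )
    effect_r <- with_seed(
      substream_seed(config$seed, r, 3),
      stats::rnorm(1, 0, config$difference_sd)
    )
    treated <- with_seed(
      substream_seed(config$seed, r, 1),
      render_arm(config, config$waviness_treated,
                 max(0, config$fiber_intensity_offset_treated + effect_r),
                 intercept)
    )
    control <- with_seed(
      substream_seed(config$seed, r, 2),
      render_arm(config, config$waviness_control,
                 config$fiber_intensity_offset_control, intercept)
    )
    rabbits[[r]] <- list(
      rabbit_id = r, intercept = intercept,
      treated = treated$image, control = control$image,
      fibers = list(treated = treated$fibers, control = control$fibers)
    )
  }
  structure(list(config = config, rabbits = rabbits),
            class = "condition_set")
}

#' @exportS3Method base::print
print.condition_set <- function(x, ...) {
  cat(sprintf(
    "condition_set '%s': %d animals, %d x %d px, expected mean diff %.1f\n",
    x$config$name, length(x$rabbits), x$config$image_size[1],
    x$config$image_size[2], x$config$expected_mean_difference
  ))
  invisible(x)
}

#' Write a condition set to disk
#'
#' Writes one 16-bit grayscale TIFF per image, named
#' `{config}_{rabbit}_{arm}.tif`, a ground-truth CSV (one row per fiber:
#' rabbit, arm, fiber id, true waviness, seed-point coordinates) and a JSON
#' manifest recording the configuration and seed.
#'
#' @param set A `condition_set`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_condition_set <- function(set, dir) {
  if (!inherits(set, "condition_set")) stop("expected a condition_set")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- set$config
  truth <- list()
  for (rb in set$rabbits) {
    for (arm in c("treated", "control")) {
      img_path <- file.path(dir, sprintf("%s_%d_%s.tif", cfg$name,
                                         rb$rabbit_id, arm))
      write_image(rb[[arm]], img_path)
      fl <- rb$fibers[[arm]]
      for (i in seq_along(fl)) {
        sp <- fiber_seed_point(fl[[i]])
        truth[[length(truth) + 1L]] <- data.frame(
          rabbit = rb$rabbit_id, arm = arm, fiber = i,
          true_waviness = fl[[i]]$true_waviness,
          seed_x = sp[1], seed_y = sp[2]
        )
      }
    }
  }
  utils::write.csv(do.call(rbind, truth),
                   file.path(dir, paste0(cfg$name, "_truth.csv")),
                   row.names = FALSE)
  manifest <- file.path(dir, paste0(cfg$name, "_manifest.json"))
  cfg_out <- cfg
  cfg_out$noise <- unclass(cfg_out$noise)
  jsonlite::write_json(unclass(cfg_out), manifest, auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}

#' Seed point for tracing a ground-truth fiber
#'
#' The centerline sample nearest the middle of the fiber, used to seed the
#' automated tracer in synthetic mode.
#'
#' @param fiber A [fiber_spec].
#' @return Numeric `c(x, y)`.
#' @export
fiber_seed_point <- function(fiber) {
  pts <- fiber$centerline$points
  unname(pts[ceiling(nrow(pts) / 2), ])
}
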