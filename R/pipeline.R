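# End-to-end round-trip runners: generate synthetic data from a preset,
# run the full analysis, and summarize how well the known ground truth is
# recovered. These are the entry points used by the reproduction script and
# the command-line interface.

#' Intensity round trip: recover the mean brightness difference
#'
#' For each of `n_seeds` replicate seeds, generates a paired condition set
#' from the preset, computes every image's mean pixel density from its
#' full-bit-range histogram, forms per-animal treated-minus-control
#' differences, and pools them. The grand mean is compared against the
#' preset's ground-truth `expected_mean_difference`.
#'
#' @param preset Preset name (see [preset_config()]) or a
#'   [generator_config] used as template.
#' @param n_rabbits Animals per seed (default 10).
#' @param n_seeds Replicate seeds (default 20).
#' @param seed Base seed; replicate seeds are derived sub-streams.
#' @param ... Further [generator_config()] overrides (e.g. `image_size`).
#' @return List of class `intensity_roundtrip`: `grand_mean`, `sd`, `se`,
#'   `n_pairs`, `expected`, `per_pair_differences`, `per_seed` (each seed's
#'   `paired_intensity_result`).
#' @export
run_intensity_roundtrip <- function(preset = "cfg-int-40", n_rabbits = 10L,
                                    n_seeds = 20L, seed = 1L, ...) {
  per_seed <- vector("list", n_seeds)
  diffs <- numeric(0)
  for (i in seq_len(n_seeds)) {
    cfg <- as_generator_config(preset, seed = substream_seed(seed, 11, i),
                               n_rabbits = n_rabbits, ...)
    set <- generate_condition_set(cfg)
    res <- condition_set_intensity(set)
    per_seed[[i]] <- res
    diffs <- c(diffs, res$per_rabbit_differences)
  }
  expected <- cfg$expected_mean_difference
  structure(
    list(preset = cfg$name, grand_mean = mean(diffs), sd = stats::sd(diffs),
         se = stats::sd(diffs) / sqrt(length(diffs)),
         n_pairs = length(diffs), expected = expected,
         per_pair_differences = diffs, per_seed = per_seed),
    class = "intensity_roundtrip"
  )
}

#' @exportS3Method base::print
print.intensity_roundtrip <- function(x, ...) {
  cat(sprintf(
    "intensity round trip [%s]: %.2f +/- %.2f counts (SE %.3f, %d pairs; ground truth %.1f)\n",
    x$preset, x$grand_mean, x$sd, x$se, x$n_pairs, x$expected
  ))
  invisible(x)
}

as_generator_config <- function(preset, ...) {
  if (inherits(preset, "generator_config")) {
    args <- unclass(preset)
    args$expected_mean_difference <- NULL
    dots <- list(...)
    args[names(dots)] <- dots
    do.call(generator_config, args)
  } else {
    preset_config(preset, ...)
  }
}

#' Waviness round trip: render, trace and recover Waviness-%
#'
#' For each replicate seed, generates `n_images` image fields per arm
#' (treated and control), traces `fibers_per_image` fibers per image from
#' the ground-truth seed points, applies the hierarchical averaging (fibers
#' within image, then images within arm) and evaluates the Waviness-%
#' formula. Reports the per-seed values and their median.
#'
#' @inheritParams run_intensity_roundtrip
#' @param n_images Image fields per arm and seed (default 10).
#' @param fibers_per_image Fibers traced per image (default 10).
#' @param trace_opts A [trace_params] or `NULL` for defaults matched to the
#'   preset's fiber width.
#' @return List of class `waviness_roundtrip`: `median_percent`,
#'   `per_seed_percent`, `truth_percent`, per-seed
#'   `waviness_percent_result`s in `per_seed`.
#' @export
run_waviness_roundtrip <- function(preset = "cfg-wav-40", n_images = 10L,
                                   fibers_per_image = 10L, n_seeds = 20L,
                                   seed = 1L, trace_opts = NULL, ...) {
  per_seed <- vector("list", n_seeds)
  pct <- numeric(n_seeds)
  for (i in seq_len(n_seeds)) {
    cfg <- as_generator_config(preset, seed = substream_seed(seed, 23, i),
                               n_rabbits = n_images, ...)
    if (is.null(trace_opts)) {
      topts <- trace_params(fiber_width_px = cfg$fiber_width)
    } else {
      topts <- trace_opts
    }
    set <- generate_condition_set(cfg)
    arm_means <- list(treated = numeric(0), control = numeric(0))
    for (rb in set$rabbits) {
      for (arm in c("treated", "control")) {
        fibers <- rb$fibers[[arm]][seq_len(min(fibers_per_image,
                                               length(rb$fibers[[arm]])))]
        traces <- lapply(fibers, function(f) {
          trace_fiber(rb[[arm]], fiber_seed_point(f), topts)
        })
        meas <- measure_fibers(traces,
                               sprintf("%s_%d_%s", cfg$name, rb$rabbit_id,
                                       arm))
        arm_means[[arm]] <- c(arm_means[[arm]], image_mean_waviness(meas))
      }
    }
    wp <- waviness_percent(
      condition_waviness(arm_means$treated, "treated"),
      condition_waviness(arm_means$control, "control")
    )
    per_seed[[i]] <- wp
    pct[i] <- wp$waviness_percent
  }
  truth <- 100 * (cfg$waviness_treated - 1) / (cfg$waviness_control - 1)
  structure(
    list(preset = cfg$name, median_percent = stats::median(pct),
         per_seed_percent = pct, truth_percent = truth,
         per_seed = per_seed),
    class = "waviness_roundtrip"
  )
}

#' @exportS3Method base::print
print.waviness_roundtrip <- function(x, ...) {
  cat(sprintf(
    "waviness round trip [%s]: median Waviness-%% %.1f over %d seeds (ground truth %.1f)\n",
    x$preset, x$median_percent, length(x$per_seed_percent), x$truth_percent
  ))
  invisible(x)
}

#' Delta-Tm round trip: recover sector shifts and the zone of effect
#'
#' For each replicate seed, generates a synthetic per-sector Tm table from
#' the preset and runs [sector_delta()] and [sector_tests()]. Reports the
#' grand mean delta-Tm per sector (pooled over seeds and animals) and how
#' often each sector came out significant.
#'
#' @param preset Tm preset name (see [tm_preset()]) or a [tm_table_config].
#' @param n_seeds Replicate seeds (default 20).
#' @param seed Base seed.
#' @param alpha Significance level for the sector tests.
#' @param ... Overrides passed to [tm_table_config()].
#' @return List of class `tm_roundtrip`: `sector_grand_mean` (named, 16),
#'   `sector_se`, `significance_rate` (fraction of seeds each sector was
#'   significant), `majority_significant` (sectors significant in more than
#'   half the seeds), `truth_shifts`.
#' @export
run_tm_roundtrip <- function(preset = "cfg-tm-40-map", n_seeds = 20L,
                             seed = 1L, alpha = 0.05, ...) {
  as_cfg <- function(s) {
    if (inherits(preset, "tm_table_config")) {
      args <- unclass(preset)
      args$seed <- s
      dots <- list(...)
      args[names(dots)] <- dots
      do.call(tm_table_config, args)
    } else {
      tm_preset(preset, seed = s, ...)
    }
  }
  all_d <- matrix(NA_real_, 0, 16)
  sig <- matrix(FALSE, n_seeds, 16)
  for (i in seq_len(n_seeds)) {
    cfg <- as_cfg(substream_seed(seed, 37, i))
    tab <- generate_tm_table(cfg)
    tests <- sector_tests(tab, alpha = alpha)
    d <- tab$treated_tm - tab$control_tm
    # pool raw per-(animal, sector) differences across seeds
    dm <- matrix(NA_real_, cfg$n_rabbits, 16)
    for (s in 1:16) dm[, s] <- d[tab$sector == s]
    all_d <- rbind(all_d, dm)
    sig[i, tests$sector] <- tests$significant
  }
  name <- if (inherits(preset, "tm_table_config")) "custom" else preset
  rate <- colMeans(sig)
  structure(
    list(preset = name,
         sector_grand_mean = stats::setNames(colMeans(all_d), 1:16),
         sector_se = stats::setNames(
           apply(all_d, 2, stats::sd) / sqrt(nrow(all_d)), 1:16),
         significance_rate = stats::setNames(rate, 1:16),
         majority_significant = which(rate > 0.5),
         truth_shifts = cfg$sector_shifts, n_tables = n_seeds),
    class = "tm_roundtrip"
  )
}

#' @exportS3Method base::print
print.tm_roundtrip <- function(x, ...) {
  cat(sprintf("delta-Tm round trip [%s]: %d tables\n", x$preset,
              x$n_tables))
  cat("  majority-significant sectors: ",
      paste(x$majority_significant, collapse = ", "), "\n", sep = "")
  top <- order(-abs(x$sector_grand_mean))[1:3]
  for (s in sort(top)) {
    cat(sprintf("  sector %d: delta-Tm %.2f (truth %.2f)\n", s,
                x$sector_grand_mean[s], x$truth_shifts[s]))
  }
  invisible(x)
}

#' Run the full synthetic reproduction study
#'
#' Runs the intensity, waviness and delta-Tm round trips on all calibrated
#' presets and assembles a comparison table of recovered values against the
#' presets' ground truth.
#'
#' @param seed Base seed.
#' @param n_seeds Replicate seeds per preset (default 20).
#' @param image_size Image side used for the rendered presets; fiber count
#'   and length are scaled proportionally from the nominal 1024-px geometry.
#' @param quiet Suppress progress output.
#' @return List of class `study_report` with the individual round-trip
#'   objects and a `comparison` data frame (`quantity`, `recovered`,
#'   `ground_truth`, `units`).
#' @export
run_study <- function(seed = 1L, n_seeds = 20L, image_size = 1024L,
                      quiet = FALSE) {
  sc <- scaled_geometry(image_size)
  say <- function(...) if (!quiet) message(...)
  say("intensity round trips ...")
  int40 <- do.call(run_intensity_roundtrip,
                   c(list("cfg-int-40", n_seeds = n_seeds, seed = seed), sc))
  int400 <- do.call(run_intensity_roundtrip,
                    c(list("cfg-int-400", n_seeds = n_seeds, seed = seed), sc))
  say("waviness round trips (render + trace) ...")
  wav40 <- do.call(run_waviness_roundtrip,
                   c(list("cfg-wav-40", n_seeds = n_seeds, seed = seed),
                     sc["image_size"], list(fiber_length = sc$fiber_length)))
  wav400 <- do.call(run_waviness_roundtrip,
                    c(list("cfg-wav-400", n_seeds = n_seeds, seed = seed),
                      sc["image_size"], list(fiber_length = sc$fiber_length)))
  say("delta-Tm round trips ...")
  tm400i <- run_tm_roundtrip("cfg-tm-400-insitu", n_seeds = n_seeds,
                             seed = seed)
  tm40m <- run_tm_roundtrip("cfg-tm-40-map", n_seeds = n_seeds, seed = seed)
  tm400m <- run_tm_roundtrip("cfg-tm-400-map", n_seeds = n_seeds,
                             seed = seed)
  comparison <- data.frame(
    quantity = c("mean pixel density difference, 40 mM",
                 "mean pixel density difference, 400 mM",
                 "Waviness-%, 40 mM", "Waviness-%, 400 mM",
                 "injection-site delta-Tm, 400 mM in-situ",
                 "sector-2 delta-Tm, 40 mM map"),
    recovered = c(int40$grand_mean, int400$grand_mean,
                  wav40$median_percent, wav400$median_percent,
                  tm400i$sector_grand_mean[2], tm40m$sector_grand_mean[2]),
    ground_truth = c(int40$expected, int400$expected,
                     wav40$truth_percent, wav400$truth_percent,
                     tm400i$truth_shifts[2], tm40m$truth_shifts[2]),
    units = c("counts", "counts", "%", "%", "degC", "degC")
  )
  structure(
    list(intensity_40 = int40, intensity_400 = int400,
         waviness_40 = wav40, waviness_400 = wav400,
         tm_400_insitu = tm400i, tm_40_map = tm40m, tm_400_map = tm400m,
         comparison = comparison, seed = seed, n_seeds = n_seeds,
         image_size = image_size),
    class = "study_report"
  )
}

# proportional scaling of the nominal 1024-px geometry to another image
# side, preserving the fiber coverage fraction (so calibrated peak
# intensities stay inside the 12-bit range)
scaled_geometry <- function(image_size) {
  f <- image_size / 1024
  list(image_size = c(image_size, image_size),
       fiber_length = round(200 * f),
       n_fibers_per_image = max(4L, round(75 * f)))
}

#' @exportS3Method base::print
print.study_report <- function(x, ...) {
  cat(sprintf("synthetic reproduction study (seed %d, %d seeds, %d px)\n",
              x$seed, x$n_seeds, x$image_size))
  print(x$comparison, row.names = FALSE, digits = 4)
  invisible(x)
}
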