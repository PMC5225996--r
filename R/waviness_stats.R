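# The waviness statistic with its hierarchical averaging.
#
# Waviness of a fiber is arc/chord (>= 1). Ten fibers are measured per image
# field and averaged; image means are then averaged within a condition
# (images, not fibers, are the replication unit). The headline statistic is
#   Waviness-% = 100 * (W_treated - 1) / (W_control - 1),
# the treated condition's excess waviness as a percentage of the control's;
# values below 100 mean crosslinking straightened the fibers.

#' Build a fiber measurement table from traced polylines
#'
#' @param traces List of [polyline]s from one image.
#' @param image_id Identifier for the image.
#' @return Data frame with `image_id`, `fiber_id`, `arc`, `chord`,
#'   `waviness`.
#' @export
measure_fibers <- function(traces, image_id) {
  if (length(traces) == 0L) stop("no traces supplied")
  do.call(rbind, lapply(seq_along(traces), function(i) {
    p <- traces[[i]]
    data.frame(image_id = image_id, fiber_id = i,
               arc = arc_length(p), chord = chord_length(p),
               waviness = fiber_waviness(p))
  }))
}

#' Mean waviness of one image field
#'
#' Arithmetic mean of the per-fiber waviness values from a single image;
#' the study protocol takes 10 fibers per field, so a different count is
#' reported as a warning but not an error.
#'
#' @param fibers Data frame as from [measure_fibers()] (single `image_id`),
#'   or a bare numeric vector of waviness values.
#' @return Mean waviness (dimensionless).
#' @export
image_mean_waviness <- function(fibers) {
  if (is.numeric(fibers)) {
    w <- fibers
  } else {
    if (!is.data.frame(fibers) || !"waviness" %in% names(fibers)) {
      stop("fibers must be a measurement data frame or numeric vector")
    }
    if (length(unique(fibers$image_id)) > 1L) {
      stop("fibers from more than one image; average per image first")
    }
    w <- fibers$waviness
  }
  if (length(w) == 0L) stop("no fiber measurements")
  if (length(w) != 10L) {
    warning("image has ", length(w), " fiber measurements (protocol: 10)")
  }
  mean(w)
}

#' Condition-level waviness summary
#'
#' Mean and sample SD over image-level means; at least two images are
#' required because the image is the replication unit.
#'
#' @param image_means Numeric vector of image-level mean waviness (>= 2).
#' @param label Condition label.
#' @return A list of class `condition_waviness` with `label`,
#'   `per_image_means`, `condition_mean`, `condition_sd`, `n_images`.
#' @export
condition_waviness <- function(image_means, label) {
  if (!is.numeric(image_means) || length(image_means) < 2L) {
    stop("need >= 2 image-level means (images are the replication unit)")
  }
  structure(
    list(label = label, per_image_means = image_means,
         condition_mean = mean(image_means),
         condition_sd = stats::sd(image_means),
         n_images = length(image_means)),
    class = "condition_waviness"
  )
}

#' Compare waviness between two arms
#'
#' Two-sided test on image-level means: paired t-test when images are
#' paired by animal (the default for the paired-eye design), Welch
#' two-sample t-test otherwise.
#'
#' @param treated_means,control_means Numeric image-level means (>= 2 each;
#'   equal lengths when paired).
#' @param paired Logical (default `TRUE`).
#' @return List with `p_value`, `statistic`, `df`, `method`.
#' @export
compare_waviness <- function(treated_means, control_means, paired = TRUE) {
  if (length(treated_means) < 2L || length(control_means) < 2L) {
    stop("need >= 2 image means per arm")
  }
  if (paired && length(treated_means) != length(control_means)) {
    stop("paired comparison needs equal numbers of images per arm")
  }
  if (paired && stats::sd(treated_means - control_means) == 0) {
    stop("degenerate test: paired differences have zero variance")
  }
  if (!paired && stats::sd(treated_means) == 0 &&
      stats::sd(control_means) == 0) {
    stop("degenerate test: both arms have zero variance")
  }
  tt <- stats::t.test(treated_means, control_means, paired = paired,
                      var.equal = FALSE)
  list(p_value = unname(tt$p.value), statistic = unname(tt$statistic),
       df = unname(tt$parameter), method = tt$method)
}

#' Waviness-% of a treated condition relative to its control
#'
#' Evaluates `100 * (W_treated - 1) / (W_control - 1)` on the condition
#' means and attaches the two-arm significance test. Undefined when the
#' control fibers are (numerically) straight.
#'
#' @param treated,control [condition_waviness] objects.
#' @param paired Passed to [compare_waviness()] (default `TRUE`).
#' @return A list of class `waviness_percent_result` with `treated`,
#'   `control`, `waviness_percent` and `p_value`.
#' @export
waviness_percent <- function(treated, control, paired = TRUE) {
  if (!inherits(treated, "condition_waviness") ||
      !inherits(control, "condition_waviness")) {
    stop("treated and control must be condition_waviness objects")
  }
  if (control$condition_mean <= 1 + 1e-6) {
    stop("Waviness-% undefined: control mean waviness <= 1 ",
         "(control fibers are straight)")
  }
  pct <- 100 * (treated$condition_mean - 1) / (control$condition_mean - 1)
  p <- tryCatch(
    compare_waviness(treated$per_image_means, control$per_image_means,
                     paired = paired)$p_value,
    error = function(e) NA_real_
  )
  structure(
    list(treated = treated, control = control,
         waviness_percent = pct, p_value = p),
    class = "waviness_percent_result"
  )
}

#' @exportS3Method base::print
print.waviness_percent_result <- function(x, ...) {
  cat(sprintf(
    "Waviness-%%: %.1f%%  (treated %.4f +/- %.4f, control %.4f +/- %.4f; p = %.4g)\n",
    x$waviness_percent, x$treated$condition_mean, x$treated$condition_sd,
    x$control$condition_mean, x$control$condition_sd, x$p_value
  ))
  invisible(x)
}
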