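# Histogram / mean-pixel-density ("brightness") statistics for paired
# treated/control image sets, and the random-intercept condition model.

#' Paired mean-pixel-density analysis
#'
#' Computes per-animal treated-minus-control differences in mean pixel
#' density, their mean and sample SD, and a two-sided paired t-test.
#'
#' @param treated,control Equal-length lists of [image16] (or numeric
#'   vectors of precomputed image means), ordered by animal so that element
#'   i of each is the same animal's pair.
#' @return A list of class `paired_intensity_result` with
#'   `per_rabbit_differences`, `mean_difference`, `sd_difference`,
#'   `p_value` and `degenerate` (`TRUE` when the differences have zero
#'   variance, in which case no t-test is possible and `p_value` is `NA`).
#' @export
paired_intensity_analysis <- function(treated, control) {
  to_means <- function(x) {
    if (is.numeric(x)) return(as.numeric(x))
    vapply(x, mean_pixel_density, numeric(1))
  }
  tm <- to_means(treated)
  cm <- to_means(control)
  if (length(tm) != length(cm)) stop("treated and control must be paired")
  if (length(tm) < 2L) stop("need >= 2 pairs")
  d <- tm - cm
  degenerate <- stats::sd(d) == 0
  p <- if (degenerate) NA_real_ else stats::t.test(d)$p.value
  structure(
    list(per_rabbit_differences = d, mean_difference = mean(d),
         sd_difference = stats::sd(d), p_value = p, n = length(d),
         degenerate = degenerate),
    class = "paired_intensity_result"
  )
}

#' @exportS3Method base::print
print.paired_intensity_result <- function(x, ...) {
  cat(sprintf(
    "paired mean pixel density: %.1f +/- %.1f counts (n = %d, p = %.3g%s)\n",
    x$mean_difference, x$sd_difference, x$n, x$p_value,
    if (x$degenerate) ", degenerate" else ""
  ))
  invisible(x)
}

#' Analyze a condition set's image brightness
#'
#' Convenience wrapper: extracts per-animal treated and control mean pixel
#' densities from a generated `condition_set` and runs
#' [paired_intensity_analysis()].
#'
#' @param set A `condition_set` from [generate_condition_set()].
#' @return A `paired_intensity_result`.
#' @export
condition_set_intensity <- function(set) {
  if (!inherits(set, "condition_set")) stop("expected a condition_set")
  paired_intensity_analysis(
    lapply(set$rabbits, `[[`, "treated"),
    lapply(set$rabbits, `[[`, "control")
  )
}

#' Random-intercept linear mixed model for condition brightness
#'
#' Fits `value ~ condition + (1 | rabbit)` to per-eye mean pixel densities,
#' with a fixed effect per condition and a random intercept per animal,
#' by maximum likelihood (default) or REML. Inference on the fixed effects
#' is Wald (normal approximation, no small-sample df correction). All
#' pairwise condition contrasts are reported.
#'
#' @param observations Data frame with columns `rabbit`, `condition`,
#'   `value` (one row per eye: the eye's mean pixel density).
#' @param reference Condition level to use as reference (default: first
#'   factor level, conventionally the untreated control).
#' @param method `"ML"` (default) or `"REML"`.
#' @return A list of class `mixed_model_fit`: `condition_effects` (named
#'   offsets vs the reference), `effect_SEs`, `pairwise_contrasts` (data
#'   frame with `a`, `b`, `estimate`, `SE`, `p_value`),
#'   `rabbit_intercept_variance`, `residual_variance`, and the underlying
#'   `lme4` fit in `$fit`.
#' @export
fit_random_intercept <- function(observations, reference = NULL,
                                 method = c("ML", "REML")) {
  method <- match.arg(method)
  need <- c("rabbit", "condition", "value")
  if (!is.data.frame(observations) || !all(need %in% names(observations))) {
    stop("observations needs columns rabbit, condition, value")
  }
  obs <- observations
  obs$condition <- factor(obs$condition)
  obs$rabbit <- factor(obs$rabbit)
  if (nlevels(obs$rabbit) < 2L) {
    stop("rabbit intercept variance unidentifiable with a single rabbit")
  }
  if (nlevels(obs$condition) < 2L) stop("need >= 2 conditions")
  if (!is.null(reference)) obs$condition <- stats::relevel(obs$condition, reference)
  tab <- table(obs$rabbit)
  if (any(tab == 0)) stop("every rabbit needs >= 1 observation")
  fit <- withCallingHandlers(
    lme4::lmer(value ~ condition + (1 | rabbit), data = obs,
               REML = (method == "REML"),
               control = lme4::lmerControl(check.conv.singular = "ignore")),
    message = function(m) invokeRestart("muffleMessage")
  )
  fe <- lme4::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  lev <- levels(obs$condition)
  # effect of each condition vs the reference (coefficient parameterization)
  eff_names <- paste0("condition", lev[-1])
  if (!all(eff_names %in% names(fe))) stop("rank-deficient condition design")
  effects <- stats::setNames(fe[eff_names], lev[-1])
  ses <- stats::setNames(sqrt(diag(V)[eff_names]), lev[-1])
  # all pairwise contrasts in the full coefficient basis
  coef_of <- function(cond) {
    v <- stats::setNames(numeric(length(fe)), names(fe))
    if (cond != lev[1]) v[paste0("condition", cond)] <- 1
    v
  }
  pairs <- utils::combn(lev, 2)
  contrasts <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[2, i]; b <- pairs[1, i]
    cvec <- coef_of(a) - coef_of(b)
    est <- sum(cvec * fe)
    se <- sqrt(drop(t(cvec) %*% V %*% cvec))
    z <- if (se > 0) est / se else Inf * sign(est)
    data.frame(a = a, b = b, estimate = est, SE = se,
               p_value = 2 * stats::pnorm(-abs(z)))
  }))
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(
    list(condition_effects = effects, effect_SEs = ses,
         pairwise_contrasts = contrasts,
         rabbit_intercept_variance = vc$vcov[vc$grp == "rabbit"],
         residual_variance = vc$vcov[vc$grp == "Residual"],
         method = method, fit = fit),
    class = "mixed_model_fit"
  )
}

#' @exportS3Method base::print
print.mixed_model_fit <- function(x, ...) {
  cat("random-intercept model (", x$method, "): condition effects vs ",
      "reference\n", sep = "")
  for (nm in names(x$condition_effects)) {
    cat(sprintf("  %s: %.3f (SE %.3f)\n", nm, x$condition_effects[[nm]],
                x$effect_SEs[[nm]]))
  }
  cat(sprintf("  rabbit intercept variance %.3f, residual variance %.3f\n",
              x$rabbit_intercept_variance, x$residual_variance))
  invisible(x)
}
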