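#' Area under the ROC curve (concordance statistic)
#'
#' Computed by the rank formula; equals the probability that a randomly
#' chosen case scores higher than a randomly chosen non-case, with ties
#' counting one-half.
#'
#' @param scores Numeric prediction scores (any monotone scale).
#' @param labels Binary outcomes (0/1); both classes must be present.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (length(scores) != length(labels)) {
    stop("scores and labels differ in length", call. = FALSE)
  }
  if (any(!labels %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop("both outcome classes must be present to compute AUC", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified percentile bootstrap confidence interval for the AUC
#'
#' Cases and non-cases are resampled separately (so every resample contains
#' both classes) and the 2.5/97.5 percentiles of the resampled AUCs are
#' reported. Reproducible under a fixed seed.
#'
#' @inheritParams auc
#' @param B Number of bootstrap resamples (at least 200; default 2000).
#' @param seed Integer seed.
#' @param level Confidence level (default 0.95).
#' @return Numeric vector `c(lower, upper)` with attribute `"B"`.
#' @export
bootstrap_auc_ci <- function(scores, labels, B = 2000L, seed = 1L,
                             level = 0.95) {
  if (B < 200L) stop("B must be at least 200", call. = FALSE)
  labels <- as.numeric(labels)
  idx1 <- which(labels == 1)
  idx0 <- which(labels == 0)
  if (!length(idx1) || !length(idx0)) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  set.seed(seed)
  stats <- vapply(seq_len(B), function(b) {
    i <- c(sample(idx1, length(idx1), replace = TRUE),
           sample(idx0, length(idx0), replace = TRUE))
    auc(scores[i], labels[i])
  }, numeric(1))
  alpha <- (1 - level) / 2
  ci <- unname(stats::quantile(stats, c(alpha, 1 - alpha)))
  attr(ci, "B") <- B
  ci
}

#' Brier score
#'
#' Mean squared difference between predicted probabilities and binary
#' outcomes; 0 is perfect.
#'
#' @param probs Predicted probabilities in \[0, 1\].
#' @param outcomes Binary outcomes (0/1).
#' @return Brier score in \[0, 1\].
#' @export
brier <- function(probs, outcomes) {
  if (length(probs) != length(outcomes)) {
    stop("probs and outcomes differ in length", call. = FALSE)
  }
  if (any(probs < 0 | probs > 1)) {
    stop("probs must lie in [0, 1]", call. = FALSE)
  }
  mean((probs - as.numeric(outcomes))^2)
}

# Recalibration fits used by CITL, slope and the unreliability test.
.recalibration_fit <- function(lp, outcomes) {
  stats::glm(outcomes ~ lp, family = stats::binomial())
}

#' Calibration-in-the-large
#'
#' The intercept of the logistic recalibration model
#' `logit P(y = 1) = a + offset(lp)`, fitted by maximum likelihood. Zero means
#' the average predicted risk matches the observed risk on the logit scale.
#' The probability-scale difference `mean(y) - mean(plogis(lp))` is attached
#' as attribute `"prob_scale_diff"`.
#'
#' @param lp Linear predictor (log-odds) of the model under assessment.
#' @param outcomes Binary outcomes; both classes must be present.
#' @return The recalibration intercept (log-odds scalar).
#' @export
calibration_in_the_large <- function(lp, outcomes) {
  outcomes <- as.numeric(outcomes)
  if (sum(outcomes) == 0 || sum(outcomes) == length(outcomes)) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  fit <- stats::glm(outcomes ~ 1 + offset(lp), family = stats::binomial())
  a <- unname(stats::coef(fit)[1L])
  attr(a, "prob_scale_diff") <- mean(outcomes) - mean(stats::plogis(lp))
  a
}

#' Calibration slope
#'
#' The slope `b` of the logistic recalibration model
#' `logit P(y = 1) = a + b * lp`. A perfect model has slope 1; slopes below 1
#' indicate over-fitted (too extreme) predictions.
#'
#' @inheritParams calibration_in_the_large
#' @return The recalibration slope.
#' @export
calibration_slope <- function(lp, outcomes) {
  outcomes <- as.numeric(outcomes)
  if (stats::var(lp) <= 0) {
    stop("linear predictor is degenerate (zero variance)", call. = FALSE)
  }
  if (sum(outcomes) == 0 || sum(outcomes) == length(outcomes)) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  unname(stats::coef(.recalibration_fit(lp, outcomes))[2L])
}

#' Two-degree-of-freedom unreliability test
#'
#' Likelihood-ratio test of perfect calibration, comparing the free
#' recalibration model `logit P = a + b * lp` against the fixed model
#' (`a = 0`, `b = 1`). Rejection indicates a statistically significant
#' departure of the calibration curve from the ideal 45-degree line.
#'
#' @inheritParams calibration_in_the_large
#' @return A list with `chi2`, `df` (always 2), and `p_value`.
#' @export
unreliability_test <- function(lp, outcomes) {
  outcomes <- as.numeric(outcomes)
  if (stats::var(lp) <= 0) {
    stop("linear predictor is degenerate (zero variance)", call. = FALSE)
  }
  fit <- .recalibration_fit(lp, outcomes)
  ll_free <- as.numeric(stats::logLik(fit))
  p0 <- stats::plogis(lp)
  ll_fixed <- sum(stats::dbinom(outcomes, 1, p0, log = TRUE))
  chi2 <- max(0, 2 * (ll_free - ll_fixed))
  list(chi2 = chi2, df = 2L,
       p_value = stats::pchisq(chi2, df = 2, lower.tail = FALSE))
}

#' Flexible calibration curve
#'
#' Local-linear (loess) smooth of the binary outcome on the predicted
#' probability, evaluated on a uniform grid restricted to the observed
#' probability range, with 95% pointwise bands from the smoother's standard
#' errors, plus optional decile group points.
#'
#' @inheritParams brier
#' @param span Loess span (default 0.75).
#' @param grid_size Number of grid points (default 100).
#' @param level Band level (default 0.95).
#' @param deciles Attach decile (mean predicted, observed rate) points?
#' @param max_fit_n Above this size the smoother is fitted on an
#'   evenly-thinned (by sorted predicted probability) subset, which bounds
#'   the memory of the standard-error computation; deterministic.
#' @return A data frame of class `calibration_curve` with columns `grid`,
#'   `observed`, `band_low`, `band_high`; decile points in attribute
#'   `"group_points"`.
#' @export
flexible_calibration_curve <- function(probs, outcomes, span = 0.75,
                                       grid_size = 100L, level = 0.95,
                                       deciles = TRUE, max_fit_n = 10000L) {
  outcomes <- as.numeric(outcomes)
  n <- length(probs)
  if (n < 50L) {
    stop("at least 50 observations are required for the calibration curve",
         call. = FALSE)
  }
  fit_p <- probs
  fit_y <- outcomes
  if (n > max_fit_n) {
    ord <- order(probs)
    idx <- ord[unique(round(seq(1, n, length.out = max_fit_n)))]
    fit_p <- probs[idx]
    fit_y <- outcomes[idx]
  }
  fit <- stats::loess(fit_y ~ fit_p, degree = 1, span = span)
  grid <- seq(min(probs), max(probs), length.out = grid_size)
  pred <- stats::predict(fit, newdata = data.frame(fit_p = grid), se = TRUE)
  z <- stats::qnorm((1 + level) / 2)
  out <- data.frame(grid = grid,
                    observed = as.numeric(pred$fit),
                    band_low = as.numeric(pred$fit - z * pred$se.fit),
                    band_high = as.numeric(pred$fit + z * pred$se.fit))
  if (deciles) {
    brk <- unique(stats::quantile(probs, probs = seq(0, 1, by = 0.1)))
    if (length(brk) > 2L) {
      grp <- cut(probs, breaks = brk, include.lowest = TRUE)
      attr(out, "group_points") <- data.frame(
        predicted = tapply(probs, grp, mean),
        observed = tapply(outcomes, grp, mean))
    }
  }
  class(out) <- c("calibration_curve", "data.frame")
  out
}

#' Wilson score confidence interval for a proportion
#'
#' @param successes Number of successes (0 to `n`).
#' @param n Number of trials (positive).
#' @param level Confidence level (default 0.95).
#' @return Numeric vector `c(lower, upper)`.
#' @export
wilson_ci <- function(successes, n, level = 0.95) {
  if (n <= 0) stop("n must be positive", call. = FALSE)
  if (successes < 0 || successes > n) {
    stop("successes must lie in [0, n]", call. = FALSE)
  }
  z <- stats::qnorm((1 + level) / 2)
  p <- successes / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Assemble the full performance panel for one validation regime
#'
#' @param probs Predicted probabilities.
#' @param lp Linear predictor on the log-odds scale (logit of `probs` for a
#'   logistic model).
#' @param outcomes Binary outcomes.
#' @param regime One of `"apparent"`, `"standard"`, `"adjusted"`,
#'   `"refitted"`.
#' @param B,seed Bootstrap settings for the AUC interval; use the same seed
#'   across regimes on one dataset to pair the resamples.
#' @param rank_scores Optional score vector used for the discrimination
#'   metrics (AUC and its bootstrap interval) in place of `probs`. An
#'   intercept update cannot change the risk ranking, so the adjusted regime
#'   passes the unadjusted scores here: this makes the regime equality of the
#'   AUC exact instead of being exposed to floating-point tie churn.
#' @return An object of class `performance_report`.
#' @export
performance_report <- function(probs, lp, outcomes,
                               regime = c("apparent", "standard", "adjusted",
                                          "refitted"),
                               B = 2000L, seed = 1L, rank_scores = NULL) {
  regime <- match.arg(regime)
  outcomes <- as.numeric(outcomes)
  if (is.null(rank_scores)) rank_scores <- probs
  a <- calibration_in_the_large(lp, outcomes)
  unrel <- unreliability_test(lp, outcomes)
  ci <- bootstrap_auc_ci(rank_scores, outcomes, B = B, seed = seed)
  structure(list(
    n = length(outcomes),
    prevalence = mean(outcomes),
    brier = brier(probs, outcomes),
    auc = auc(rank_scores, outcomes),
    auc_ci = ci,
    citl = as.numeric(a),
    citl_prob_scale = attr(a, "prob_scale_diff"),
    slope = calibration_slope(lp, outcomes),
    unreliability_chi2 = unrel$chi2,
    unreliability_df = unrel$df,
    unreliability_p = unrel$p_value,
    regime = regime),
    class = "performance_report")
}

#' @export
print.performance_report <- function(x, digits = 2, ...) {
  cat(sprintf("Performance report [%s regime] (n = %d, prevalence = %.1f%%)\n",
              x$regime, x$n, 100 * x$prevalence))
  cat(sprintf("  Brier score              %.*f\n", digits, x$brier))
  cat(sprintf("  AUC (95%% CI)             %.*f (%.*f, %.*f)\n", digits, x$auc,
              digits, x$auc_ci[1], digits, x$auc_ci[2]))
  cat(sprintf("  Calibration-in-the-large %.*f\n", digits, x$citl))
  cat(sprintf("  Calibration slope        %.*f\n", digits, x$slope))
  cat(sprintf("  Unreliability chi2 (df=%d) %.*f, p = %.3g\n",
              x$unreliability_df, digits, x$unreliability_chi2,
              x$unreliability_p))
  invisible(x)
}

#' Serialize a performance report to JSON
#'
#' @param report A `performance_report`.
#' @param path Optional output file.
#' @return JSON string, invisibly when written to file.
#' @export
report_to_json <- function(report, path = NULL) {
  obj <- unclass(report)
  obj$auc_ci <- list(lower = report$auc_ci[1], upper = report$auc_ci[2])
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
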