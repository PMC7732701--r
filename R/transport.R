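.new_validation_run <- function(model_in, regime, model_out, report, curve) {
  structure(list(model_in = model_in, regime = regime, model_out = model_out,
                 report = report, curve = curve),
            class = "validation_run")
}

#' @export
print.validation_run <- function(x, ...) {
  cat(sprintf("Validation run (%s regime)\n", x$regime))
  print(x$report)
  invisible(x)
}

.run_with_model <- function(model_in, model_out, regime, x, y, B, seed, span,
                            rank_scores = NULL) {
  lp <- linear_predictor(model_out, x)
  p <- stats::plogis(lp)
  report <- performance_report(p, lp, y, regime = regime, B = B, seed = seed,
                               rank_scores = rank_scores)
  curve <- if (length(y) >= 50L) {
    flexible_calibration_curve(p, y, span = span)
  } else NULL
  .new_validation_run(model_in, regime, model_out, report, curve)
}

#' Standard external validation
#'
#' Applies a frozen risk model to a new cohort and computes the full
#' discrimination/calibration panel.
#'
#' @param model A [logistic_risk_model()] fitted elsewhere.
#' @param x Validation design matrix matching the model's terms.
#' @param y Validation outcomes (0/1).
#' @param B,seed Bootstrap settings; keep them identical across regimes on
#'   one dataset so the AUC resamples are paired.
#' @param span Loess span for the calibration curve.
#' @return A `validation_run` (`model_out` identical to `model`).
#' @export
standard_external_validation <- function(model, x, y, B = 2000L, seed = 1L,
                                         span = 0.75) {
  .run_with_model(model, model, "standard", x, y, B, seed, span)
}

#' Intercept-adjusted (recalibration-in-the-large) validation
#'
#' Shifts the model intercept by the calibration-in-the-large estimated on
#' the validation cohort, leaving all slope coefficients untouched, then
#' recomputes the performance panel with the updated model on the same data.
#' By construction the adjusted model's calibration-in-the-large is zero,
#' and the discrimination metrics are computed on the unadjusted scores
#' (an intercept shift cannot change the ranking), so the AUC and its
#' bootstrap interval are identical to the standard regime's.
#'
#' @inheritParams standard_external_validation
#' @return A `validation_run` whose `model_out` differs from `model` only in
#'   the intercept.
#' @export
adjust_intercept <- function(model, x, y, B = 2000L, seed = 1L, span = 0.75) {
  lp <- linear_predictor(model, x)
  a <- as.numeric(calibration_in_the_large(lp, y))
  adjusted <- model
  adjusted$intercept <- model$intercept + a
  adjusted$meta$intercept_adjustment <- a
  .run_with_model(model, adjusted, "adjusted", x, y, B, seed, span,
                  rank_scores = stats::plogis(lp))
}

#' Refitted-model validation
#'
#' Re-estimates every coefficient of the model on the validation cohort
#' (unpenalized maximum likelihood by default) and reports in-sample
#' performance. With `penalty = 0` the in-sample calibration-in-the-large is
#' 0 and the slope is 1 by the maximum-likelihood score equations.
#'
#' @inheritParams standard_external_validation
#' @param penalty L2 penalty for the refit (default 0).
#' @return A `validation_run` with the refitted model as `model_out`.
#' @export
refit <- function(model, x, y, penalty = 0, B = 2000L, seed = 1L,
                  span = 0.75) {
  terms <- names(model$coefficients)
  x <- as.matrix(x)
  missing <- setdiff(terms, colnames(x))
  if (length(missing)) {
    stop("validation design lacks model term(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  refitted <- fit_penalized(x[, terms, drop = FALSE], y, penalty = penalty)
  .run_with_model(model, refitted, "refitted", x, y, B, seed, span)
}

#' Run all three validation regimes on one cohort
#'
#' Standard, intercept-adjusted, and refitted validation on the identical
#' dataset with a shared bootstrap seed, so regime comparisons are paired.
#'
#' @inheritParams refit
#' @return A named list of three `validation_run` objects
#'   (`standard`, `adjusted`, `refitted`).
#' @export
validate_all <- function(model, x, y, penalty = 0, B = 2000L, seed = 1L,
                         span = 0.75) {
  list(standard = standard_external_validation(model, x, y, B, seed, span),
       adjusted = adjust_intercept(model, x, y, B, seed, span),
       refitted = refit(model, x, y, penalty, B, seed, span))
}

#' Tabulate performance across validation regimes
#'
#' Builds the four-row metric table (Brier, AUC with CI,
#' calibration-in-the-large, calibration slope) with one column per regime.
#'
#' @param runs A list of `validation_run` objects (at least one).
#' @param digits Rounding for the formatted table (default 2).
#' @return A data frame with a `measure` column and one column per regime;
#'   the unrounded values are attached as attribute `"numeric"`.
#' @export
validation_table <- function(runs, digits = 2) {
  runs <- Filter(function(r) inherits(r, "validation_run"), runs)
  if (!length(runs)) stop("need at least one validation run", call. = FALSE)
  reports <- lapply(runs, function(r) r$report)
  regimes <- vapply(reports, function(r) r$regime, character(1))
  num <- sapply(reports, function(r) {
    c(brier = r$brier, auc = r$auc, citl = r$citl, slope = r$slope)
  })
  num <- matrix(num, nrow = 4L,
                dimnames = list(c("brier", "auc", "citl", "slope"), regimes))
  fmt <- function(v) formatC(round(v, digits), format = "f", digits = digits)
  cols <- lapply(seq_along(reports), function(j) {
    r <- reports[[j]]
    c(fmt(r$brier),
      sprintf("%s (%s, %s)", fmt(r$auc), fmt(r$auc_ci[1]), fmt(r$auc_ci[2])),
      fmt(r$citl),
      fmt(r$slope))
  })
  out <- data.frame(
    measure = c("Brier score", "AUC (95% CI)", "Calibration-in-the-large",
                "Calibration slope"),
    stats::setNames(as.data.frame(cols), regimes),
    check.names = FALSE)
  attr(out, "numeric") <- num
  out
}

#' Age-restricted sensitivity analyses
#'
#' Re-applies the sample selection for each baseline age window and runs all
#' three validation regimes on the resulting subsample.
#'
#' @param cohort Coded cohort with `age_baseline`, `depressed_baseline`, the
#'   seven predictors, and `depressed_followup`.
#' @param model The frozen risk model to transport.
#' @param age_windows List of inclusive integer `c(min, max)` windows.
#' @param penalty,B,seed,span Passed through to the regimes.
#' @return A named list (one element per window, name `"min-max"`) of regime
#'   triples as returned by [validate_all()], each with the window's
#'   `selection_flow` attached as element `flow`. Windows selecting nobody
#'   are skipped with a warning; windows with fewer than 50 records warn but
#'   still run.
#' @export
sensitivity_by_age <- function(cohort, model,
                               age_windows = list(c(15L, 15L), c(14L, 16L),
                                                  c(11L, 17L)),
                               penalty = 0, B = 2000L, seed = 1L,
                               span = 0.75) {
  out <- list()
  for (w in age_windows) {
    key <- paste0(w[1], "-", w[2])
    sel <- suppressWarnings(select_analysis_sample(cohort, w[1], w[2]))
    n <- nrow(sel$sample)
    if (n == 0L) {
      warning("age window ", key, " selects no records; skipped",
              call. = FALSE)
      next
    }
    if (n < 50L) {
      warning("age window ", key, " selects only ", n, " records",
              call. = FALSE)
    }
    x <- encode_design(sel$sample)
    runs <- validate_all(model, x, sel$sample$depressed_followup,
                         penalty = penalty, B = B, seed = seed, span = span)
    runs$flow <- sel$flow
    out[[key]] <- runs
  }
  out
}
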