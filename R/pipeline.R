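#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run: cohort sizes, penalty
#' selection, bootstrap replicates, smoother span, sensitivity age windows,
#' report rounding, and all named seeds (simulation, cross-validation,
#' bootstrap). Every source of randomness in the pipeline flows from these
#' seeds.
#'
#' @param n_development Development cohort size.
#' @param penalty Fixed ridge penalty for the development fit, or `NULL` to
#'   select it by 10-fold cross-validated deviance.
#' @param penalty_grid Candidate penalties when cross-validating.
#' @param refit_penalty Penalty for the refitted regime (default 0,
#'   unpenalized maximum likelihood).
#' @param bootstrap_B Bootstrap replicates for AUC intervals.
#' @param span Loess span for calibration curves.
#' @param age_windows Sensitivity-analysis age windows (inclusive).
#' @param rounding Decimal places in the formatted report table.
#' @param seed_simulation,seed_cv,seed_bootstrap Named seeds.
#' @param raw_spec Raw-survey generator spec for the validation cohort.
#' @param output_dir Optional directory; when given, reports, model JSON,
#'   audit JSON and figures are written there.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_development = 10000L,
                            penalty = NULL,
                            penalty_grid = c(0, 0.5, 1, 2, 4, 8, 16, 32),
                            refit_penalty = 0,
                            bootstrap_B = 2000L,
                            span = 0.75,
                            age_windows = list(c(15L, 15L), c(11L, 17L)),
                            rounding = 2,
                            seed_simulation = 1001L,
                            seed_cv = 2002L,
                            seed_bootstrap = 3003L,
                            raw_spec = lagos_raw_spec(),
                            output_dir = NULL) {
  structure(list(n_development = as.integer(n_development),
                 penalty = penalty, penalty_grid = penalty_grid,
                 refit_penalty = refit_penalty,
                 bootstrap_B = as.integer(bootstrap_B), span = span,
                 age_windows = age_windows, rounding = rounding,
                 seed_simulation = as.integer(seed_simulation),
                 seed_cv = as.integer(seed_cv),
                 seed_bootstrap = as.integer(seed_bootstrap),
                 raw_spec = raw_spec, output_dir = output_dir),
            class = "pipeline_config")
}

#' Run the full validation pipeline
#'
#' Simulates the development and validation cohorts, codes the raw survey
#' records, applies the sample-selection filters, fits the penalized
#' development model, transports it through the standard, intercept-adjusted
#' and refitted regimes, tabulates the metric panel, and runs the
#' age-window sensitivity analyses. Deterministic under a fixed config.
#'
#' @param config A [pipeline_config()].
#' @return A bundle list: `model`, `penalty`, `runs` (the three regimes),
#'   `table`, `flow`, `sensitivity`, `validation_sample`, and a stage `log`
#'   (character vector). When `config$output_dir` is set, reports, model and
#'   audit JSON, the table CSV and ROC/calibration figures are also written
#'   there.
#' @export
run_full_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- character(0)
  say <- function(...) {
    line <- sprintf(...)
    message(line)
    log <<- c(log, line)
  }

  say("simulate: development cohort n=%d (seed %d)", config$n_development,
      config$seed_simulation)
  dev <- generate_development_cohort(
    development_cohort_spec(n = config$n_development),
    seed = config$seed_simulation)
  x_dev <- encode_design(dev)
  y_dev <- dev$depressed_followup

  say("simulate: raw validation survey n=%d (seed %d)",
      config$raw_spec$n_followed_up, config$seed_simulation + 1L)
  raw <- generate_raw_survey(config$raw_spec,
                             seed = config$seed_simulation + 1L)
  coded <- code_cohort(raw$records)
  say("code: %d records coded, %d excluded for missingness", nrow(coded),
      attr(coded, "n_excluded_missing"))
  sel <- select_analysis_sample(coded, config$raw_spec$age_min,
                                config$raw_spec$age_max)
  say("select: %d -> %d in age range -> %d final", sel$flow$followed_up,
      sel$flow$in_age_range, sel$flow$final)
  x_val <- encode_design(sel$sample)
  y_val <- sel$sample$depressed_followup

  if (is.null(config$penalty)) {
    cv <- cv_penalty(x_dev, y_dev, penalties = config$penalty_grid,
                     seed = config$seed_cv)
    pen <- cv$penalty
    say("fit: penalty %s selected by 10-fold CV (seed %d)", format(pen),
        config$seed_cv)
  } else {
    pen <- config$penalty
    say("fit: fixed penalty %s", format(pen))
  }
  model <- fit_penalized(x_dev, y_dev, penalty = pen)
  say("fit: converged in %d iterations on n=%d", model$meta$iterations,
      model$meta$n)

  runs <- validate_all(model, x_val, y_val, penalty = config$refit_penalty,
                       B = config$bootstrap_B, seed = config$seed_bootstrap,
                       span = config$span)
  tab <- validation_table(runs, digits = config$rounding)
  say("validate: standard/adjusted/refitted regimes on n=%d (bootstrap B=%d, seed %d)",
      length(y_val), config$bootstrap_B, config$seed_bootstrap)

  sens <- sensitivity_by_age(coded, model, age_windows = config$age_windows,
                             penalty = config$refit_penalty,
                             B = config$bootstrap_B,
                             seed = config$seed_bootstrap,
                             span = config$span)
  for (key in names(sens)) {
    say("sensitivity: age window %s, n=%d", key, sens[[key]]$flow$final)
  }

  bundle <- list(model = model, penalty = pen, runs = runs, table = tab,
                 flow = sel$flow, sensitivity = sens,
                 validation_sample = sel$sample, log = log)

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(config$output_dir, f)
    model_to_json(model, out("model.json"))
    flow_to_json(sel$flow, out("selection_flow.json"))
    utils::write.csv(tab, out("validation_table.csv"), row.names = FALSE)
    for (nm in names(runs)) {
      report_to_json(runs[[nm]]$report, out(paste0("report_", nm, ".json")))
    }
    p_std <- predict_prob(model, x_val)
    ggplot2::ggsave(out("roc_standard.png"),
                    plot_roc(p_std, y_val), width = 5, height = 5, dpi = 150)
    ggplot2::ggsave(out("roc_refitted.png"),
                    plot_roc(predict_prob(runs$refitted$model_out, x_val),
                             y_val), width = 5, height = 5, dpi = 150)
    for (nm in names(runs)) {
      if (!is.null(runs[[nm]]$curve)) {
        ggplot2::ggsave(out(paste0("calibration_", nm, ".png")),
                        plot_calibration(runs[[nm]]$curve),
                        width = 5, height = 5, dpi = 150)
      }
    }
    writeLines(log, out("pipeline_log.txt"))
    say("report: artifacts written to %s", config$output_dir)
  }
  bundle
}

# Empirical ROC points (thresholds swept from high to low).
.roc_points <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  labels <- as.numeric(labels)[ord]
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  tpr <- c(0, cumsum(labels == 1) / n1)
  fpr <- c(0, cumsum(labels == 0) / n0)
  data.frame(fpr = fpr, tpr = tpr)
}

#' ROC curve figure
#'
#' True positive rate against false positive rate, with the chance diagonal
#' and an AUC annotation.
#'
#' @inheritParams auc
#' @return A ggplot object.
#' @export
plot_roc <- function(scores, labels) {
  if (!length(scores)) stop("no scores to plot", call. = FALSE)
  pts <- .roc_points(scores, labels)
  a <- auc(scores, labels)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::annotate("text", x = 0.7, y = 0.1,
                      label = sprintf("AUC = %.2f", a)) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "False positive rate", y = "True positive rate") +
    ggplot2::theme_minimal()
}

#' Calibration plot
#'
#' Model predictions on the x axis, smoothed observed proportion on the y
#' axis with 95% pointwise limits, the ideal 45-degree line, and decile
#' group points when available.
#'
#' @param curve A `calibration_curve` from [flexible_calibration_curve()].
#' @return A ggplot object.
#' @export
plot_calibration <- function(curve) {
  if (is.null(curve) || !nrow(curve)) {
    stop("empty calibration curve", call. = FALSE)
  }
  gp <- attr(curve, "group_points")
  p <- ggplot2::ggplot(as.data.frame(curve),
                       ggplot2::aes(x = .data$grid, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey70") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$band_low,
                                      ymax = .data$band_high),
                         fill = "grey85") +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "Predicted probability", y = "Observed proportion") +
    ggplot2::theme_minimal()
  if (!is.null(gp)) {
    p <- p + ggplot2::geom_point(data = gp,
                                 ggplot2::aes(x = .data$predicted,
                                              y = .data$observed),
                                 shape = 4)
  }
  p
}
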