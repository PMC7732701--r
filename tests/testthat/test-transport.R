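# One moderate validation setup shared across regime tests.
make_transport_fixture <- function(n = 4000, seed = 61) {
  coh <- generate_coded_cohort(validation_cohort_spec(n = n), seed = seed)
  list(x = encode_design(coh), y = coh$depressed_followup,
       true_model = attr(coh, "true_model"))
}

test_that("validating a model on its own generating population is near-perfectly calibrated", {
  coh <- generate_coded_cohort(validation_cohort_spec(n = 30000), seed = 70)
  run <- standard_external_validation(attr(coh, "true_model"),
                                      encode_design(coh),
                                      coh$depressed_followup, B = 200)
  expect_equal(run$report$slope, 1, tolerance = 0.1)
  expect_lt(abs(run$report$citl), 0.1)
  expect_identical(run$model_out, run$model_in)
})

test_that("a development-prevalence model transported to the higher-prevalence cohort shows positive CITL", {
  dev <- generate_development_cohort(development_cohort_spec(n = 30000),
                                     seed = 71)
  model <- fit_penalized(encode_design(dev), dev$depressed_followup)
  fx <- make_transport_fixture(n = 10000, seed = 72)
  run <- standard_external_validation(model, fx$x, fx$y, B = 200)
  expect_gt(run$report$citl, 0.5)
})

test_that("standard and adjusted regimes report bit-identical AUC", {
  for (s in c(61, 62, 63)) {
    fx <- make_transport_fixture(n = 2500, seed = s)
    model <- inject_miscalibration(fx$true_model, k = 0.7, drift = 0.6)
    std <- standard_external_validation(model, fx$x, fx$y, B = 200)
    adj <- adjust_intercept(model, fx$x, fx$y, B = 200)
    expect_identical(std$report$auc, adj$report$auc)
    expect_identical(std$report$auc_ci, adj$report$auc_ci)
  }
})

test_that("intercept adjustment zeroes CITL, only moves the intercept, and is idempotent", {
  fx <- make_transport_fixture()
  model <- inject_miscalibration(fx$true_model, k = 1, drift = 1.2)
  adj <- adjust_intercept(model, fx$x, fx$y, B = 200)
  expect_lt(abs(adj$report$citl), 1e-6)
  expect_equal(adj$model_out$coefficients, model$coefficients)
  expect_false(adj$model_out$intercept == model$intercept)

  again <- adjust_intercept(adj$model_out, fx$x, fx$y, B = 200)
  expect_lt(abs(again$model_out$intercept - adj$model_out$intercept), 1e-6)

  calibrated <- adjust_intercept(fx$true_model, fx$x, fx$y, B = 200)
  expect_lt(abs(calibrated$model_out$intercept - fx$true_model$intercept),
            0.15)
})

test_that("unpenalized refit satisfies the in-sample MLE score identities", {
  fx <- make_transport_fixture()
  run <- refit(fx$true_model, fx$x, fx$y, penalty = 0, B = 200)
  expect_lt(abs(run$report$citl), 1e-6)
  expect_lt(abs(run$report$slope - 1), 1e-6)
  expect_setequal(names(run$model_out$coefficients),
                  names(fx$true_model$coefficients))
  # penalized refit is supported and shrinks away from the MLE identities
  run_pen <- refit(fx$true_model, fx$x, fx$y, penalty = 30, B = 200)
  expect_gt(run_pen$report$slope, 1)
})

test_that("adjustment does not worsen the Brier score materially on shifted cohorts", {
  worse <- 0
  for (s in 1:10) {
    coh <- generate_coded_cohort(validation_cohort_spec(n = 3000),
                                 seed = 500 + s)
    model <- inject_miscalibration(attr(coh, "true_model"), k = 1,
                                   drift = -1.4)
    x <- encode_design(coh)
    y <- coh$depressed_followup
    b_std <- brier(predict_prob(model, x), y)
    adj <- adjust_intercept(model, x, y, B = 200)
    b_adj <- brier(predict_prob(adj$model_out, x), y)
    if (b_adj > b_std + 0.002) worse <- worse + 1
  }
  expect_equal(worse, 0)
})

test_that("refitting recovers discrimination lost to coefficient drift", {
  for (s in 1:5) {
    # validation outcomes generated from shrunken coefficients
    coh <- generate_coded_cohort(
      validation_cohort_spec(n = 4000, shrinkage_k = 0.64), seed = 600 + s)
    x <- encode_design(coh)
    y <- coh$depressed_followup
    model <- logistic_risk_model(attr(coh, "true_model")$intercept,
                                 default_coefficients())
    std <- standard_external_validation(model, x, y, B = 200)
    ref <- refit(model, x, y, B = 200)
    expect_gte(ref$report$auc, std$report$auc - 0.01)
  }
})

test_that("the validation table mirrors the individual reports after rounding", {
  fx <- make_transport_fixture()
  model <- inject_miscalibration(fx$true_model, k = 0.8, drift = 0.5)
  runs <- validate_all(model, fx$x, fx$y, B = 200)
  tab <- validation_table(runs)
  expect_equal(dim(tab), c(4L, 4L))
  expect_equal(names(tab), c("measure", "standard", "adjusted", "refitted"))
  num <- attr(tab, "numeric")
  expect_equal(num["brier", "standard"], runs$standard$report$brier)
  expect_equal(num["slope", "refitted"], runs$refitted$report$slope)
  expect_equal(tab$standard[1],
               formatC(round(runs$standard$report$brier, 2), format = "f",
                       digits = 2))
  expect_equal(tab$adjusted[3], "0.00")
  expect_error(validation_table(list()), "at least one")
})

test_that("age-window sensitivity reruns the full regime triple per window", {
  coh <- generate_coded_cohort(
    validation_cohort_spec(n = 3000,
                           age_distribution = c("13" = 0.1, "14" = 0.25,
                                                "15" = 0.3, "16" = 0.25,
                                                "17" = 0.1)),
    seed = 81)
  model <- inject_miscalibration(attr(coh, "true_model"), k = 0.8,
                                 drift = 0.4)
  sens <- sensitivity_by_age(coh, model,
                             age_windows = list(c(15L, 15L), c(14L, 16L),
                                                c(11L, 17L)),
                             B = 200)
  expect_setequal(names(sens), c("15-15", "14-16", "11-17"))
  for (key in names(sens)) {
    expect_setequal(setdiff(names(sens[[key]]), "flow"),
                    c("standard", "adjusted", "refitted"))
    expect_s3_class(sens[[key]]$flow, "selection_flow")
  }
  expect_equal(sens[["11-17"]]$flow$final, nrow(coh))

  # the main-analysis window reproduces a direct run bit for bit
  sel <- select_analysis_sample(coh, 14, 16)
  direct <- validate_all(model, encode_design(sel$sample),
                         sel$sample$depressed_followup, B = 200)
  expect_identical(sens[["14-16"]]$standard$report,
                   direct$standard$report)
  expect_identical(sens[["14-16"]]$refitted$model_out$coefficients,
                   direct$refitted$model_out$coefficients)

  expect_warning(
    none <- sensitivity_by_age(coh, model,
                               age_windows = list(c(20L, 21L)), B = 200),
    "skipped")
  expect_length(none, 0)
})
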