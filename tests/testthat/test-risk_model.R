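test_that("design encoding is deterministic dummy coding with reference none", {
  ref <- data.frame(sex_female = 0, maltreatment = "none", school_failure = 0,
                    social_isolation = 0, fights = 0, ran_away = 0,
                    drug_use = 0)
  expect_equal(as.numeric(encode_design(ref)), rep(0, 8))
  expect_equal(colnames(encode_design(ref)), design_terms())

  sev <- ref; sev$maltreatment <- "severe"
  row <- encode_design(sev)
  expect_equal(as.numeric(row[1, "maltreatment_probable"]), 0)
  expect_equal(as.numeric(row[1, "maltreatment_severe"]), 1)

  two <- ref; two$maltreatment <- "probable"; two$drug_use <- 1
  expect_equal(sum(encode_design(two)), 2)

  bad <- ref; bad$maltreatment <- "extreme"
  expect_error(encode_design(bad), "maltreatment")
  expect_error(encode_design(ref[, -1]), "sex_female")
})

test_that("unpenalized intercept-only fit recovers the observed log-odds", {
  y <- c(rep(1, 31), rep(0, 969))
  m <- fit_penalized(NULL, y, penalty = 0)
  expect_equal(m$intercept, qlogis(0.031), tolerance = 1e-8)
  expect_length(m$coefficients, 0)
})

test_that("a very large penalty shrinks all slopes to zero", {
  set.seed(3)
  x <- cbind(a = rbinom(300, 1, 0.4), b = rbinom(300, 1, 0.2))
  y <- rbinom(300, 1, plogis(-1 + x[, 1] - 0.5 * x[, 2]))
  m <- fit_penalized(x, y, penalty = 1e7)
  expect_true(all(abs(m$coefficients) < 1e-3))
  expect_equal(m$intercept, qlogis(mean(y)), tolerance = 1e-3)
})

test_that("penalty-0 fit matches the brute-force likelihood grid and glm", {
  # hand dataset, one predictor, n = 8
  x8 <- matrix(c(0, 0, 0, 0, 1, 1, 1, 1), ncol = 1,
               dimnames = list(NULL, "x"))
  y8 <- c(0, 0, 0, 1, 0, 1, 1, 1)
  m8 <- fit_penalized(x8, y8, penalty = 0)
  oracle8 <- grid_logistic_mle(x8, y8)
  expect_equal(unname(c(m8$intercept, m8$coefficients)), oracle8,
               tolerance = 1e-3)

  # two-predictor toys against the grid maximizer and stats::glm
  set.seed(9)
  for (rep in 1:3) {
    x <- cbind(a = rbinom(60, 1, 0.5), b = rbinom(60, 1, 0.3))
    y <- rbinom(60, 1, plogis(-0.5 + 0.9 * x[, 1] - 0.7 * x[, 2]))
    if (sum(y) < 3 || sum(y) > 57) next
    m <- fit_penalized(x, y, penalty = 0)
    fitted <- unname(c(m$intercept, m$coefficients))
    expect_equal(fitted, grid_logistic_mle(x, y), tolerance = 1e-3)
    expect_equal(fitted, unname(coef(glm(y ~ x, family = binomial))),
                 tolerance = 1e-6)
  }
})

test_that("ridge solution agrees with glmnet at matched penalty scaling", {
  set.seed(14)
  n <- 400
  x <- cbind(a = rbinom(n, 1, 0.4), b = rbinom(n, 1, 0.25),
             c = rbinom(n, 1, 0.1))
  y <- rbinom(n, 1, plogis(-1.5 + 0.8 * x[, 1] + 0.5 * x[, 2] + x[, 3]))
  pen <- 6
  m <- fit_penalized(x, y, penalty = pen)
  gn <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                       lambda = pen / n, standardize = FALSE, thresh = 1e-14)
  expect_equal(unname(c(m$intercept, m$coefficients)),
               as.numeric(glmnet::coef.glmnet(gn)), tolerance = 1e-5)
})

test_that("coefficient shrinkage is monotone in the penalty", {
  set.seed(21)
  x <- encode_design(make_predictors(800, seed = 21))
  y <- rbinom(800, 1, plogis(-2 + drop(x %*% default_coefficients())))
  pens <- c(0, 1, 2, 4, 8, 16, 32)
  mags <- sapply(pens, function(p) abs(fit_penalized(x, y, penalty = p)$coefficients))
  for (j in seq_len(ncol(mags) - 1)) {
    expect_true(all(mags[, j + 1] <= mags[, j] + 1e-8))
  }
})

test_that("linear predictor and probabilities follow the logistic identities", {
  m <- logistic_risk_model(-2, c(a = 0.5, b = 0.7))
  x <- matrix(c(1, 1), nrow = 1, dimnames = list(NULL, c("a", "b")))
  expect_equal(linear_predictor(m, x), -0.8)
  expect_equal(predict_prob(m, x), 0.3100, tolerance = 1e-4)

  zero <- matrix(c(0, 0), nrow = 1, dimnames = list(NULL, c("a", "b")))
  expect_equal(linear_predictor(m, zero), m$intercept)
  expect_equal(predict_prob(logistic_risk_model(0, c(a = 1)),
                            matrix(0, 1, 1, dimnames = list(NULL, "a"))), 0.5)

  wrong <- matrix(0, 1, 2, dimnames = list(NULL, c("a", "zz")))
  expect_error(linear_predictor(m, wrong), "missing.*b.*extra.*zz")
})

test_that("probability is strictly increasing in each coefficient-indicator product", {
  set.seed(2)
  for (rep in 1:10) {
    beta <- runif(3, -2, 2)
    m <- logistic_risk_model(runif(1, -2, 0),
                             setNames(beta, c("a", "b", "c")))
    x <- matrix(rbinom(30, 1, 0.5), ncol = 3,
                dimnames = list(NULL, c("a", "b", "c")))
    j <- sample(3, 1)
    bumped <- m
    bumped$coefficients[j] <- bumped$coefficients[j] + 0.5
    on_rows <- x[, j] == 1
    if (!any(on_rows)) next
    expect_true(all(predict_prob(bumped, x)[on_rows] >
                      predict_prob(m, x)[on_rows]))
  }
})

test_that("separation at penalty 0 errors with advice, and a positive penalty rescues it", {
  x <- matrix(c(rep(0, 10), rep(1, 10)), ncol = 1,
              dimnames = list(NULL, "x"))
  y <- c(rep(0, 10), rep(1, 10))
  expect_error(fit_penalized(x, y, penalty = 0), "penalty")
  m <- fit_penalized(x, y, penalty = 1)
  expect_true(is.finite(m$coefficients["x"]))
  expect_error(fit_penalized(x, rep(1, 20)), "non-case")
})

test_that("rebuilding on predictor subsets refits rather than deletes coefficients", {
  set.seed(31)
  coh <- generate_development_cohort(development_cohort_spec(n = 20000),
                                     seed = 31, eleven_predictors = TRUE)
  spec_marg <- attr(coh, "spec")$predictor_marginals
  drop4 <- attr(coh, "unavailable_predictors")
  x <- deprisk:::.design_from_coded(coh, spec_marg)
  y <- coh$depressed_followup

  full <- fit_penalized(x, y, penalty = 0)
  reduced <- rebuild_without_predictors(x, y, drop = drop4, penalty = 0)
  expect_false(any(drop4 %in% names(reduced$coefficients)))
  expect_setequal(names(reduced$coefficients), design_terms())
  # retained signs match the (all-positive) generating signs
  expect_true(all(reduced$coefficients > 0))
  # a genuine refit: coefficients move relative to the full model
  expect_false(isTRUE(all.equal(reduced$coefficients[design_terms()],
                                full$coefficients[design_terms()])))

  same <- rebuild_without_predictors(x, y, drop = character(0), penalty = 0)
  expect_equal(same$coefficients, full$coefficients, tolerance = 1e-10)

  expect_warning(
    only_int <- rebuild_without_predictors(
      x[, design_terms()], y,
      drop = c("sex_female", "maltreatment", "school_failure",
               "social_isolation", "fights", "ran_away", "drug_use"),
      penalty = 0),
    "intercept-only")
  expect_equal(only_int$intercept, qlogis(mean(y)), tolerance = 1e-8)

  expect_error(rebuild_without_predictors(x, y, drop = "nope"), "unknown")
})

test_that("cross-validated penalty selection is reproducible and sensible", {
  set.seed(8)
  x <- encode_design(make_predictors(1500, seed = 8))
  y <- rbinom(1500, 1, plogis(-2.2 + drop(x %*% default_coefficients())))
  cv1 <- cv_penalty(x, y, penalties = c(0, 2, 8, 32), nfolds = 5, seed = 99)
  cv2 <- cv_penalty(x, y, penalties = c(0, 2, 8, 32), nfolds = 5, seed = 99)
  expect_identical(cv1, cv2)
  expect_true(cv1$penalty %in% c(0, 2, 8, 32))
  expect_length(cv1$cv_deviance, 4)
})

test_that("models serialize to JSON and back without loss", {
  m <- fit_penalized(encode_design(make_predictors(400, seed = 5)),
                     rbinom(400, 1, 0.2), penalty = 2)
  path <- withr::local_tempfile(fileext = ".json")
  model_to_json(m, path)
  m2 <- model_from_json(path)
  expect_equal(m2$intercept, m$intercept)
  expect_equal(m2$coefficients, m$coefficients)
  expect_equal(m2$penalty, m$penalty)
})
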