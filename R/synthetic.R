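#' Default predictor marginals for the validation setting
#'
#' Marginal prevalences of the seven predictors in the school cohort:
#' roughly half female, school failure in about a quarter of students, and
#' rarer risk markers (fights, drug use, social isolation, running away),
#' with maltreatment split none/probable/severe.
#'
#' @return Named list: binary predictors as scalar probabilities,
#'   `maltreatment` as a named probability vector over its three levels.
#' @export
default_marginals <- function() {
  list(sex_female = 0.494,
       maltreatment = c(none = 0.749, probable = 0.184, severe = 0.067),
       school_failure = 0.258,
       social_isolation = 0.044,
       fights = 0.039,
       ran_away = 0.023,
       drug_use = 0.060)
}

#' Default generating coefficients (log-odds)
#'
#' Moderate risk-factor effects on the design terms, chosen to yield
#' discrimination in the low 0.6s at the default marginals.
#'
#' @return Named numeric vector over [design_terms()].
#' @export
default_coefficients <- function() {
  c(sex_female = 0.62, maltreatment_probable = 0.35,
    maltreatment_severe = 0.90, school_failure = 0.55,
    social_isolation = 0.60, fights = 0.50, ran_away = 0.70,
    drug_use = 0.55)
}

#' Cohort generator specification
#'
#' @param n Cohort size.
#' @param predictor_marginals Named list of marginals (see
#'   [default_marginals()]); extra binary predictors may be added as scalar
#'   entries.
#' @param coefficients Named generating coefficients over the design terms
#'   implied by the marginals.
#' @param target_prevalence Target mean outcome probability; the generating
#'   intercept is solved so the population mean equals this value.
#' @param shrinkage_k Multiplier applied to the generating slopes (>0).
#' @param intercept_drift Log-odds shift bookkept inside the generating
#'   intercept (the solved intercept absorbs it so the prevalence target is
#'   always met).
#' @param baseline_depression_rate Probability of being depressed at baseline
#'   (coded cohorts default to 0, i.e. an analysis-ready population).
#' @param age_distribution Named probability vector over integer baseline
#'   ages.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n,
                        predictor_marginals = default_marginals(),
                        coefficients = default_coefficients(),
                        target_prevalence = 0.118,
                        shrinkage_k = 1,
                        intercept_drift = 0,
                        baseline_depression_rate = 0,
                        age_distribution = c("14" = 0.30, "15" = 0.36,
                                             "16" = 0.22, "13" = 0.06,
                                             "17" = 0.06)) {
  stopifnot(n >= 1, shrinkage_k > 0,
            target_prevalence > 0, target_prevalence < 1,
            baseline_depression_rate >= 0, baseline_depression_rate < 1)
  for (nm in names(predictor_marginals)) {
    p <- predictor_marginals[[nm]]
    if (any(p <= 0) || any(p >= 1) || (length(p) > 1 &&
                                       abs(sum(p) - 1) > 1e-8)) {
      stop("marginal for '", nm, "' must lie in (0,1) and sum to 1 if a ",
           "level vector", call. = FALSE)
    }
  }
  structure(list(n = as.integer(n),
                 predictor_marginals = predictor_marginals,
                 coefficients = coefficients,
                 target_prevalence = target_prevalence,
                 shrinkage_k = shrinkage_k,
                 intercept_drift = intercept_drift,
                 baseline_depression_rate = baseline_depression_rate,
                 age_distribution = age_distribution),
            class = "cohort_spec")
}

#' Spec for the validation-setting cohort (follow-up prevalence 11.8%)
#'
#' @param n Cohort size (default 1928, the analysis-sample size).
#' @param ... Overrides passed to [cohort_spec()].
#' @return A `cohort_spec`.
#' @export
validation_cohort_spec <- function(n = 1928L, ...) {
  cohort_spec(n = n, target_prevalence = 0.118, ...)
}

#' Spec for the development-setting cohort (prevalence 3.1%)
#'
#' @param n Cohort size (default 10000).
#' @param ... Overrides passed to [cohort_spec()].
#' @return A `cohort_spec`.
#' @export
development_cohort_spec <- function(n = 10000L, ...) {
  cohort_spec(n = n, target_prevalence = 0.031,
              age_distribution = c("15" = 1), ...)
}

# Enumerate the finite predictor design space implied by the marginals:
# returns the design matrix of all cells and their probabilities under
# independence.
.enumerate_cells <- function(marginals) {
  levels <- lapply(marginals, function(p) {
    if (length(p) > 1L) names(p) else c(0, 1)
  })
  cells <- expand.grid(levels, stringsAsFactors = FALSE)
  names(cells) <- names(marginals)
  w <- rep(1, nrow(cells))
  cols <- list()
  for (nm in names(marginals)) {
    p <- marginals[[nm]]
    if (length(p) > 1L) {
      w <- w * p[cells[[nm]]]
      for (lev in names(p)[-1L]) {
        cols[[paste0(nm, "_", lev)]] <- as.numeric(cells[[nm]] == lev)
      }
    } else {
      v <- as.numeric(cells[[nm]])
      w <- w * ifelse(v == 1, p, 1 - p)
      cols[[nm]] <- v
    }
  }
  list(x = do.call(cbind, cols), w = unname(w))
}

#' Solve the generating intercept for a target prevalence
#'
#' Finds the intercept c such that the population mean of
#' `plogis(c + x %*% coefficients)` over the independent predictor
#' distribution equals the target. The expectation is computed exactly by
#' enumerating the finite predictor design space; the root is found by
#' bisection to 1e-6.
#'
#' @param coefficients Named generating coefficients.
#' @param marginals Predictor marginals as in [cohort_spec()].
#' @param target Target mean outcome probability in (0, 1).
#' @return The intercept (log-odds scalar).
#' @export
solve_intercept_for_prevalence <- function(coefficients, marginals, target) {
  if (target <= 0 || target >= 1) {
    stop("target prevalence must lie in (0, 1)", call. = FALSE)
  }
  cells <- .enumerate_cells(marginals)
  missing <- setdiff(names(coefficients), colnames(cells$x))
  if (length(missing)) {
    stop("marginals do not cover coefficient term(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  eta0 <- drop(cells$x[, names(coefficients), drop = FALSE] %*% coefficients)
  f <- function(c) sum(cells$w * stats::plogis(c + eta0)) - target
  lo <- -40; hi <- 40
  if (f(lo) > 0 || f(hi) < 0) {
    stop("cannot bracket the target prevalence; achievable range (",
         format(stats::plogis(lo)), ", ", format(stats::plogis(hi)), ")",
         call. = FALSE)
  }
  while (hi - lo > 1e-6) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Draw n coded predictor rows from the marginals.
.draw_predictors <- function(n, marginals) {
  out <- list()
  for (nm in names(marginals)) {
    p <- marginals[[nm]]
    if (length(p) > 1L) {
      out[[nm]] <- factor(sample(names(p), n, replace = TRUE, prob = p),
                          levels = names(p), ordered = nm == "maltreatment")
    } else {
      out[[nm]] <- stats::rbinom(n, 1L, p)
    }
  }
  as.data.frame(out)
}

# Design matrix for arbitrary marginal-defined predictors (the seven core
# predictors go through encode_design's fixed order; extras are appended).
.design_from_coded <- function(coded, marginals) {
  x <- encode_design(coded)
  extra <- setdiff(names(marginals), names(default_marginals()))
  for (nm in extra) {
    x <- cbind(x, as.numeric(coded[[nm]]))
    colnames(x)[ncol(x)] <- nm
  }
  x
}

#' Generate a coded synthetic cohort
#'
#' Draws independent predictors at the spec marginals, then draws the
#' follow-up outcome from `plogis(c* + k * x %*% beta + drift)` where the
#' intercept `c*` is solved so the population mean probability equals the
#' spec's target prevalence. The actual generating model (intercept and
#' effective slopes) is attached as attribute `"true_model"`.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; identical spec and seed give identical cohorts.
#' @return Coded cohort data frame with the seven predictors (plus any
#'   extras), `age_baseline`, `depressed_baseline`, `depressed_followup`.
#' @export
generate_coded_cohort <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  n <- spec$n
  coded <- .draw_predictors(n, spec$predictor_marginals)
  coded$age_baseline <- as.integer(sample(
    names(spec$age_distribution), n, replace = TRUE,
    prob = spec$age_distribution))
  coded$depressed_baseline <- if (spec$baseline_depression_rate > 0) {
    stats::rbinom(n, 1L, spec$baseline_depression_rate)
  } else rep(0L, n)
  eff <- spec$shrinkage_k * spec$coefficients
  c_solved <- solve_intercept_for_prevalence(eff, spec$predictor_marginals,
                                             spec$target_prevalence)
  x <- .design_from_coded(coded, spec$predictor_marginals)
  eta <- drop(c_solved + x[, names(eff), drop = FALSE] %*% eff)
  coded$depressed_followup <- stats::rbinom(n, 1L, stats::plogis(eta))
  attr(coded, "true_model") <- logistic_risk_model(
    intercept = c_solved, coefficients = eff,
    meta = list(generator = "synthetic", seed = seed,
                shrinkage_k = spec$shrinkage_k,
                intercept_drift = spec$intercept_drift,
                target_prevalence = spec$target_prevalence))
  attr(coded, "spec") <- spec
  coded
}

#' Generate a validation-setting coded cohort
#'
#' @param spec A [cohort_spec()]; defaults to [validation_cohort_spec()].
#' @param seed Integer seed.
#' @return A coded cohort (see [generate_coded_cohort()]).
#' @export
generate_validation_cohort <- function(spec = validation_cohort_spec(),
                                       seed = 1L) {
  generate_coded_cohort(spec, seed)
}

#' Generate a development-setting coded cohort
#'
#' Optionally adds four extra binary predictors (poor relationship with
#' mother/father, poor parental relationship, skin colour), flagged as
#' unavailable in the validation setting, to exercise predictor-subset
#' rebuilds.
#'
#' @param spec A [cohort_spec()]; defaults to [development_cohort_spec()].
#' @param seed Integer seed.
#' @param eleven_predictors Add the four extra predictors?
#' @return A coded cohort; when `eleven_predictors = TRUE` the extra
#'   predictor names are attached as attribute `"unavailable_predictors"`.
#' @export
generate_development_cohort <- function(spec = development_cohort_spec(),
                                        seed = 1L,
                                        eleven_predictors = FALSE) {
  if (eleven_predictors) {
    extra_marg <- list(poor_relationship_mother = 0.15,
                       poor_relationship_father = 0.20,
                       poor_parental_relationship = 0.18,
                       skin_color = 0.30)
    extra_coef <- c(poor_relationship_mother = 0.45,
                    poor_relationship_father = 0.35,
                    poor_parental_relationship = 0.40,
                    skin_color = 0.25)
    spec <- cohort_spec(
      n = spec$n,
      predictor_marginals = c(spec$predictor_marginals, extra_marg),
      coefficients = c(spec$coefficients, extra_coef),
      target_prevalence = spec$target_prevalence,
      shrinkage_k = spec$shrinkage_k,
      intercept_drift = spec$intercept_drift,
      baseline_depression_rate = spec$baseline_depression_rate,
      age_distribution = spec$age_distribution)
  }
  out <- generate_coded_cohort(spec, seed)
  if (eleven_predictors) {
    attr(out, "unavailable_predictors") <-
      c("poor_relationship_mother", "poor_relationship_father",
        "poor_parental_relationship", "skin_color")
  }
  out
}

#' Inject miscalibration into a risk model
#'
#' Multiplies all slope coefficients by `k` and shifts the intercept by
#' `drift`. Validating the modified model on data generated from the
#' original recovers slope about `1/k` and calibration-in-the-large about
#' `-drift`.
#'
#' @param model A [logistic_risk_model()].
#' @param k Positive coefficient multiplier.
#' @param drift Log-odds intercept shift.
#' @return The modified model.
#' @export
inject_miscalibration <- function(model, k = 1, drift = 0) {
  stopifnot(inherits(model, "logistic_risk_model"), k > 0)
  model$coefficients <- model$coefficients * k
  model$intercept <- model$intercept + drift
  model$meta$injected <- list(k = k, drift = drift)
  model
}

#' Specification of the packaged raw-survey fixture
#'
#' Encodes the documented selection flow of the school cohort: 3171 students
#' followed up, 2321 aged 14-16 at baseline, 393 of those depressed at
#' baseline, leaving a final analysis sample of 1928 (976 male, 952 female).
#' These counts are met exactly by construction; the seed only shuffles
#' record order and item-level realizations.
#'
#' @param target_prevalence Follow-up depression prevalence target among the
#'   generated population.
#' @return A list of class `raw_survey_spec`.
#' @export
lagos_raw_spec <- function(target_prevalence = 0.118) {
  structure(list(
    n_followed_up = 3171L,
    n_in_age = 2321L,
    n_baseline_depressed = 393L,
    final_n = 1928L,
    final_males = 976L,
    final_females = 952L,
    age_min = 14L, age_max = 16L,
    in_age_probs = c("14" = 0.40, "15" = 0.37, "16" = 0.23),
    out_age_probs = c("12" = 0.05, "13" = 0.50, "17" = 0.35, "18" = 0.10),
    out_of_range_baseline_rate = 0.17,
    male_rate_other = 0.506,
    predictor_marginals = default_marginals(),
    coefficients = default_coefficients(),
    target_prevalence = target_prevalence),
    class = "raw_survey_spec")
}

# Nine-item symptom matrix consistent with a given depression status vector:
# depressed rows get >= 5 positives including a core symptom, non-depressed
# rows get <= 4 positives.
.make_symptom_items <- function(depressed) {
  n <- length(depressed)
  items <- matrix(0L, nrow = n, ncol = 9L)
  for (i in seq_len(n)) {
    if (depressed[i]) {
      k <- sample(5:9, 1L, prob = c(0.35, 0.30, 0.20, 0.10, 0.05))
      core <- sample(1:2, 1L)
      rest <- sample(setdiff(1:9, core), k - 1L)
      items[i, c(core, rest)] <- 1L
    } else {
      k <- sample(0:4, 1L, prob = c(0.40, 0.25, 0.18, 0.10, 0.07))
      if (k > 0L) items[i, sample(1:9, k)] <- 1L
    }
  }
  items
}

# Raw (item-level) answers consistent with coded maltreatment levels.
.raw_maltreatment <- function(malt) {
  n <- length(malt)
  dv <- abuse <- character(n)
  lives <- character(n)
  u <- stats::runif(n)
  for (i in seq_len(n)) {
    if (malt[i] == "severe") {
      if (u[i] < 0.5) {
        dv[i] <- "a_lot"
        abuse[i] <- sample(c("no", "a_little", "a_lot"), 1L,
                           prob = c(0.5, 0.3, 0.2))
      } else {
        abuse[i] <- "a_lot"
        dv[i] <- sample(c("no", "a_little"), 1L, prob = c(0.6, 0.4))
      }
      lives[i] <- sample(c("yes", "no"), 1L, prob = c(0.85, 0.15))
    } else if (malt[i] == "probable") {
      if (u[i] < 0.5) {
        dv[i] <- "a_little"; abuse[i] <- "a_little"; lives[i] <- "yes"
      } else {
        dv[i] <- sample(c("no", "a_little"), 1L)
        abuse[i] <- if (dv[i] == "a_little") "no" else
          sample(c("no", "a_little"), 1L)
        lives[i] <- "no"
      }
    } else {
      lives[i] <- "yes"
      if (u[i] < 0.85) {
        dv[i] <- "no"; abuse[i] <- "no"
      } else if (u[i] < 0.93) {
        dv[i] <- "a_little"; abuse[i] <- "no"
      } else {
        dv[i] <- "no"; abuse[i] <- "a_little"
      }
    }
  }
  data.frame(domestic_violence = dv, physical_abuse = abuse,
             lives_with_biological_parent = lives)
}

# Raw substance-frequency answers consistent with the drug-use flag.
.raw_substances <- function(drug_use) {
  n <- length(drug_use)
  alc <- cig <- mar <- rep("none", n)
  pos <- which(drug_use == 1L)
  for (i in pos) {
    which_sub <- sample(1:3, 1L, prob = c(0.7, 0.2, 0.1))
    lev <- sample(c("a_little", "a_lot"), 1L, prob = c(0.8, 0.2))
    if (which_sub == 1L) alc[i] <- lev
    else if (which_sub == 2L) cig[i] <- lev
    else mar[i] <- lev
  }
  data.frame(alcohol_freq = alc, cigarette_freq = cig, marijuana_freq = mar)
}

#' Generate raw survey records with the packaged selection flow
#'
#' Emits item-level student records whose coded values reproduce a coded
#' cohort exactly under [code_cohort()], and whose selection counts under
#' [select_analysis_sample()] match the spec's flow exactly (by
#' construction): 3171 followed up, 2321 in the 14-16 age window, 393 of
#' those baseline-depressed, 1928 final (976 male / 952 female) under the
#' packaged defaults.
#'
#' @param spec A [lagos_raw_spec()].
#' @param seed Integer seed (shuffles order and item-level realizations
#'   only; the flow counts are deterministic).
#' @return A list with `records` (raw data frame) and `flow` (the expected
#'   `selection_flow`).
#' @export
generate_raw_survey <- function(spec = lagos_raw_spec(), seed = 1L) {
  stopifnot(inherits(spec, "raw_survey_spec"))
  if (spec$final_n != spec$n_in_age - spec$n_baseline_depressed ||
      spec$final_males + spec$final_females != spec$final_n) {
    stop("inconsistent selection-flow counts in spec", call. = FALSE)
  }
  set.seed(seed)
  n <- spec$n_followed_up
  in_age <- rep(FALSE, n)
  in_age[sample(n, spec$n_in_age)] <- TRUE
  age <- integer(n)
  age[in_age] <- as.integer(sample(names(spec$in_age_probs), spec$n_in_age,
                                   replace = TRUE,
                                   prob = spec$in_age_probs))
  age[!in_age] <- as.integer(sample(names(spec$out_age_probs),
                                    n - spec$n_in_age, replace = TRUE,
                                    prob = spec$out_age_probs))
  dep_base <- rep(FALSE, n)
  idx_in <- which(in_age)
  dep_base[sample(idx_in, spec$n_baseline_depressed)] <- TRUE
  dep_base[!in_age] <- stats::runif(n - spec$n_in_age) <
    spec$out_of_range_baseline_rate

  sex <- character(n)
  final_idx <- which(in_age & !dep_base)
  sex[final_idx] <- sample(c(rep("male", spec$final_males),
                             rep("female", spec$final_females)))
  other_idx <- setdiff(seq_len(n), final_idx)
  sex[other_idx] <- ifelse(stats::runif(length(other_idx)) <
                             spec$male_rate_other, "male", "female")

  coded <- .draw_predictors(n, spec$predictor_marginals)
  # the coded sex must agree with the raw sex column
  coded$sex_female <- as.integer(sex == "female")

  eff <- spec$coefficients
  c_solved <- solve_intercept_for_prevalence(
    eff, spec$predictor_marginals, spec$target_prevalence)
  x <- encode_design(coded)
  eta <- drop(c_solved + x[, names(eff), drop = FALSE] %*% eff)
  dep_fu <- stats::rbinom(n, 1L, stats::plogis(eta)) == 1L

  base_items <- .make_symptom_items(dep_base)
  fu_items <- .make_symptom_items(dep_fu)
  malt_raw <- .raw_maltreatment(as.character(coded$maltreatment))
  subst_raw <- .raw_substances(coded$drug_use)
  fights_raw <- t(vapply(coded$fights, function(f) {
    if (f == 1L) c("yes", "yes")
    else {
      pick <- sample(1:3, 1L, prob = c(0.7, 0.2, 0.1))
      list(c("no", "no"), c("yes", "no"), c("no", "yes"))[[pick]]
    }
  }, character(2)))
  close_friends <- ifelse(coded$social_isolation == 1L, 0L,
                          sample(1:10, n, replace = TRUE,
                                 prob = 10:1 / sum(10:1)))

  raw <- data.frame(
    id = sprintf("S%04d", seq_len(n)),
    age_baseline = age,
    sex = sex,
    school_year = "SS1",
    close_friends = close_friends,
    repeated_class = ifelse(coded$school_failure == 1L, "yes", "no"),
    started_fight = fights_raw[, 1L],
    hurt_someone = fights_raw[, 2L],
    ran_away_many_days = ifelse(coded$ran_away == 1L, "yes", "no"),
    stringsAsFactors = FALSE)
  raw <- cbind(raw, subst_raw, malt_raw)
  colnames(base_items) <- paste0("dep_base_", 1:9)
  colnames(fu_items) <- paste0("dep_fu_", 1:9)
  raw <- cbind(raw, as.data.frame(base_items), as.data.frame(fu_items))
  raw <- raw[sample(n), , drop = FALSE]
  rownames(raw) <- NULL

  flow <- structure(list(followed_up = n,
                         in_age_range = spec$n_in_age,
                         baseline_depressed_excluded =
                           spec$n_baseline_depressed,
                         final = spec$final_n,
                         age_min = spec$age_min, age_max = spec$age_max),
                    class = "selection_flow")
  list(records = raw, flow = flow)
}

#' Write a cohort to CSV
#'
#' Deterministic plain-text serialization (no row names, no quoting beyond
#' what CSV requires).
#'
#' @param cohort A cohort data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort from CSV
#'
#' @param path CSV path written by [write_cohort_csv()].
#' @return A data frame; a `maltreatment` column, if present, is restored as
#'   an ordered factor.
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("maltreatment" %in% names(df)) {
    df$maltreatment <- factor(df$maltreatment,
                              levels = .maltreatment_levels, ordered = TRUE)
  }
  df
}
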