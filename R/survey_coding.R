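#' @keywords internal
"_PACKAGE"

# Shared level sets for raw survey answers.
.freq_levels <- c("none", "a_little", "a_lot")
.exposure_levels <- c("no", "a_little", "a_lot")
.yn_levels <- c("yes", "no")
.sex_levels <- c("male", "female")
.maltreatment_levels <- c("none", "probable", "severe")

.check_levels <- function(x, levels, field) {
  bad <- !is.na(x) & !(x %in% levels)
  if (any(bad)) {
    stop(sprintf("invalid value(s) in '%s': %s (allowed: %s)",
                 field, paste(unique(x[bad]), collapse = ", "),
                 paste(levels, collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

#' Classify depression from nine DSM-IV symptom items
#'
#' Applies the DSM-IV major-depression cut-off to a vector of nine binary
#' symptom indicators: a respondent is classified as depressed when five or
#' more items are positive and at least one of the two core symptoms
#' (item 1 = depressed mood, item 2 = anhedonia) is among them.
#'
#' @param items Either a numeric vector of length 9 with entries in \{0, 1\}
#'   (one respondent), or a matrix/data frame with 9 columns (one row per
#'   respondent).
#' @return For a single respondent, a list with `positive_item_count`,
#'   `core_symptom_present`, and `depressed`; for multiple respondents, a
#'   data frame with those columns.
#' @export
classify_depression <- function(items) {
  if (is.data.frame(items)) items <- as.matrix(items)
  if (is.matrix(items)) {
    if (ncol(items) != 9L) {
      stop("symptom item matrix must have exactly 9 columns, got ",
           ncol(items), call. = FALSE)
    }
    if (any(!items %in% c(0, 1))) {
      stop("symptom items must be 0 or 1", call. = FALSE)
    }
    count <- as.integer(rowSums(items))
    core <- items[, 1L] == 1 | items[, 2L] == 1
    return(data.frame(positive_item_count = count,
                      core_symptom_present = core,
                      depressed = count >= 5L & core))
  }
  if (length(items) != 9L) {
    stop("symptom items must have exactly 9 entries, got ", length(items),
         call. = FALSE)
  }
  if (any(!items %in% c(0, 1))) {
    stop("symptom items must be 0 or 1", call. = FALSE)
  }
  count <- as.integer(sum(items))
  core <- items[1L] == 1 || items[2L] == 1
  list(positive_item_count = count,
       core_symptom_present = core,
       depressed = count >= 5L && core)
}

#' Derive the childhood maltreatment predictor
#'
#' Three ordered levels. `severe`: "a lot" of domestic violence or physical
#' abuse. `probable`: "a little" of both, or not living with a biological
#' parent. Everything else codes as `none`; precedence is
#' severe > probable > none.
#'
#' @param domestic_violence,physical_abuse Exposure levels
#'   (`"no"`, `"a_little"`, `"a_lot"`).
#' @param lives_with_parent `"yes"` or `"no"`.
#' @return An ordered factor with levels none < probable < severe.
#' @export
derive_maltreatment <- function(domestic_violence, physical_abuse,
                                lives_with_parent) {
  .check_levels(domestic_violence, .exposure_levels, "domestic_violence")
  .check_levels(physical_abuse, .exposure_levels, "physical_abuse")
  .check_levels(lives_with_parent, .yn_levels, "lives_with_biological_parent")
  severe <- domestic_violence == "a_lot" | physical_abuse == "a_lot"
  probable <- (domestic_violence == "a_little" & physical_abuse == "a_little") |
    lives_with_parent == "no"
  out <- ifelse(severe, "severe", ifelse(probable, "probable", "none"))
  factor(out, levels = .maltreatment_levels, ordered = TRUE)
}

#' Derive the drug-use predictor
#'
#' Positive when the respondent reports using any of alcohol, cigarettes, or
#' marijuana "a little" or "a lot".
#'
#' @param alcohol,cigarettes,marijuana Frequency levels
#'   (`"none"`, `"a_little"`, `"a_lot"`).
#' @return Integer 0/1.
#' @export
derive_drug_use <- function(alcohol, cigarettes, marijuana) {
  .check_levels(alcohol, .freq_levels, "alcohol_freq")
  .check_levels(cigarettes, .freq_levels, "cigarette_freq")
  .check_levels(marijuana, .freq_levels, "marijuana_freq")
  as.integer(alcohol != "none" | cigarettes != "none" | marijuana != "none")
}

#' Derive the social-isolation predictor
#'
#' A respondent with zero close friends is socially isolated.
#'
#' @param close_friends Non-negative integer count of close friends.
#' @return Integer 0/1.
#' @export
derive_social_isolation <- function(close_friends) {
  if (any(!is.na(close_friends) & close_friends < 0)) {
    stop("'close_friends' must be non-negative", call. = FALSE)
  }
  as.integer(close_friends == 0)
}

#' Derive the physical-fights predictor
#'
#' Positive only when the respondent both started a fight and hurt someone
#' on purpose.
#'
#' @param started_fight,hurt_someone `"yes"` or `"no"`.
#' @return Integer 0/1.
#' @export
derive_fights <- function(started_fight, hurt_someone) {
  .check_levels(started_fight, .yn_levels, "started_fight")
  .check_levels(hurt_someone, .yn_levels, "hurt_someone")
  as.integer(started_fight == "yes" & hurt_someone == "yes")
}

#' Derive the direct-mapping predictors
#'
#' School failure (ever repeated a class), ran away from home for many days,
#' and biological sex coded as a female indicator.
#'
#' @param record A data frame with columns `repeated_class`,
#'   `ran_away_many_days` (`"yes"`/`"no"`), and `sex` (`"male"`/`"female"`).
#' @return A data frame with columns `school_failure`, `ran_away`,
#'   `sex_female`.
#' @export
derive_simple_flags <- function(record) {
  .check_levels(record$repeated_class, .yn_levels, "repeated_class")
  .check_levels(record$ran_away_many_days, .yn_levels, "ran_away_many_days")
  .check_levels(record$sex, .sex_levels, "sex")
  data.frame(school_failure = as.integer(record$repeated_class == "yes"),
             ran_away = as.integer(record$ran_away_many_days == "yes"),
             sex_female = as.integer(record$sex == "female"))
}

#' Code a raw survey cohort into model-ready predictors and outcomes
#'
#' Converts item-level records into the seven harmonized predictors plus
#' baseline and follow-up depression status. Records with a missing value in
#' any coding input are excluded (complete-case analysis); the number of
#' exclusions is attached as attribute `n_excluded_missing`.
#'
#' @param raw A data frame of raw student records; see [generate_raw_survey()]
#'   for the column dictionary.
#' @return A coded data frame with columns `id`, `age_baseline`, `sex_female`,
#'   `maltreatment`, `school_failure`, `social_isolation`, `fights`,
#'   `ran_away`, `drug_use`, `depressed_baseline`, `depressed_followup`.
#' @export
code_cohort <- function(raw) {
  base_items <- as.matrix(raw[paste0("dep_base_", 1:9)])
  fu_items <- as.matrix(raw[paste0("dep_fu_", 1:9)])
  flags <- derive_simple_flags(raw)
  coded <- data.frame(
    id = raw$id,
    age_baseline = as.integer(raw$age_baseline),
    sex_female = flags$sex_female,
    maltreatment = derive_maltreatment(raw$domestic_violence,
                                       raw$physical_abuse,
                                       raw$lives_with_biological_parent),
    school_failure = flags$school_failure,
    social_isolation = derive_social_isolation(raw$close_friends),
    fights = derive_fights(raw$started_fight, raw$hurt_someone),
    ran_away = flags$ran_away,
    drug_use = derive_drug_use(raw$alcohol_freq, raw$cigarette_freq,
                               raw$marijuana_freq),
    depressed_baseline = as.integer(classify_depression(base_items)$depressed),
    depressed_followup = as.integer(classify_depression(fu_items)$depressed)
  )
  complete <- stats::complete.cases(coded)
  out <- coded[complete, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded_missing") <- sum(!complete)
  out
}

#' Apply the analysis-sample selection filters
#'
#' Restricts a coded cohort to the baseline age window and removes students
#' already depressed at baseline, returning the filtered cohort together with
#' a selection-flow audit of the counts at each stage.
#'
#' @param cohort Coded cohort data frame with columns `age_baseline` and
#'   `depressed_baseline`.
#' @param age_min,age_max Inclusive integer bounds on baseline age.
#' @return A list with `sample` (the filtered cohort, original order
#'   preserved) and `flow` (a `selection_flow` object with counts
#'   `followed_up`, `in_age_range`, `baseline_depressed_excluded`, `final`).
#' @export
select_analysis_sample <- function(cohort, age_min = 14L, age_max = 16L) {
  stopifnot(is.data.frame(cohort),
            all(c("age_baseline", "depressed_baseline") %in% names(cohort)))
  in_age <- cohort$age_baseline >= age_min & cohort$age_baseline <= age_max
  aged <- cohort[in_age, , drop = FALSE]
  keep <- aged$depressed_baseline == 0L
  final <- aged[keep, , drop = FALSE]
  rownames(final) <- NULL
  flow <- structure(
    list(followed_up = nrow(cohort),
         in_age_range = nrow(aged),
         baseline_depressed_excluded = sum(!keep),
         final = nrow(final),
         age_min = age_min, age_max = age_max),
    class = "selection_flow")
  if (nrow(final) == 0L) {
    warning("selection yielded an empty analysis sample", call. = FALSE)
  }
  list(sample = final, flow = flow)
}

#' @export
print.selection_flow <- function(x, ...) {
  cat(sprintf("Sample selection (baseline age %d-%d):\n", x$age_min, x$age_max))
  cat(sprintf("  followed up             %6d\n", x$followed_up))
  cat(sprintf("  in age range            %6d\n", x$in_age_range))
  cat(sprintf("  baseline depressed      %6d (excluded)\n",
              x$baseline_depressed_excluded))
  cat(sprintf("  final analysis sample   %6d\n", x$final))
  invisible(x)
}

#' Serialize a selection-flow audit to JSON
#'
#' @param flow A `selection_flow` object.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to file.
#' @export
flow_to_json <- function(flow, path = NULL) {
  json <- jsonlite::toJSON(unclass(flow), auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
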