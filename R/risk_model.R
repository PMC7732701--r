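#' Design-matrix column order for the seven-predictor model
#'
#' Six binary indicators plus two dummy indicators for maltreatment
#' (reference level `none`).
#'
#' @return Character vector of design term names.
#' @export
design_terms <- function() {
  c("sex_female", "maltreatment_probable", "maltreatment_severe",
    "school_failure", "social_isolation", "fights", "ran_away", "drug_use")
}

# Map a predictor name to the design columns it owns.
.predictor_columns <- function(predictor) {
  if (predictor == "maltreatment") {
    c("maltreatment_probable", "maltreatment_severe")
  } else {
    predictor
  }
}

#' Encode predictor vectors as a numeric design matrix
#'
#' Deterministic fixed-order 0/1 encoding of the seven predictors;
#' maltreatment enters as two mutually exclusive dummies with `none` as the
#' reference.
#'
#' @param predictors Data frame with columns `sex_female`, `maltreatment`
#'   (levels `none`/`probable`/`severe`), `school_failure`,
#'   `social_isolation`, `fights`, `ran_away`, `drug_use`.
#' @return Numeric matrix with columns [design_terms()].
#' @export
encode_design <- function(predictors) {
  needed <- c("sex_female", "maltreatment", "school_failure",
              "social_isolation", "fights", "ran_away", "drug_use")
  missing <- setdiff(needed, names(predictors))
  if (length(missing)) {
    stop("missing predictor column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  malt <- as.character(predictors$maltreatment)
  .check_levels(malt, .maltreatment_levels, "maltreatment")
  bin <- c("sex_female", "school_failure", "social_isolation", "fights",
           "ran_away", "drug_use")
  for (col in bin) {
    if (any(!predictors[[col]] %in% c(0, 1))) {
      stop("predictor '", col, "' must be 0/1", call. = FALSE)
    }
  }
  x <- cbind(sex_female = as.numeric(predictors$sex_female),
             maltreatment_probable = as.numeric(malt == "probable"),
             maltreatment_severe = as.numeric(malt == "severe"),
             school_failure = as.numeric(predictors$school_failure),
             social_isolation = as.numeric(predictors$social_isolation),
             fights = as.numeric(predictors$fights),
             ran_away = as.numeric(predictors$ran_away),
             drug_use = as.numeric(predictors$drug_use))
  x
}

#' Construct a logistic risk model object
#'
#' @param intercept Log-odds intercept.
#' @param coefficients Named numeric vector of log-odds slopes (may be empty
#'   for an intercept-only model).
#' @param penalty Non-negative L2 penalty strength used at fitting time.
#' @param meta List of fit provenance (n, iterations, tol, converged, ...).
#' @return An object of class `logistic_risk_model`.
#' @export
logistic_risk_model <- function(intercept, coefficients = numeric(0),
                                penalty = 0, meta = list()) {
  stopifnot(is.numeric(intercept), length(intercept) == 1L,
            is.finite(intercept), penalty >= 0)
  if (length(coefficients)) {
    if (is.null(names(coefficients)) || anyDuplicated(names(coefficients))) {
      stop("coefficients must have unique names", call. = FALSE)
    }
    if (any(!is.finite(coefficients))) {
      stop("coefficients must be finite", call. = FALSE)
    }
  }
  structure(list(intercept = unname(intercept),
                 coefficients = coefficients,
                 penalty = penalty,
                 meta = meta),
            class = "logistic_risk_model")
}

#' @export
print.logistic_risk_model <- function(x, ...) {
  cat("Penalized logistic risk model (L2 penalty =", format(x$penalty), ")\n")
  cat("  intercept:", format(round(x$intercept, 4)), "\n")
  if (length(x$coefficients)) {
    cat("  coefficients (log-odds):\n")
    print(round(x$coefficients, 4))
  } else {
    cat("  intercept-only model\n")
  }
  invisible(x)
}

# Penalized log-likelihood: sum(y*eta - log(1+exp(eta))) - penalty/2 * sum(beta^2)
.pen_loglik <- function(beta, x1, y, penalty) {
  eta <- drop(x1 %*% beta)
  sum(y * eta - log1p(exp(eta))) - penalty / 2 * sum(beta[-1L]^2)
}

#' Fit a ridge-penalized logistic regression
#'
#' Maximizes the Bernoulli log-likelihood minus `penalty/2 * sum(beta^2)` over
#' the slope coefficients (the intercept is never penalized) by Newton
#' iteration with step-halving. With `penalty = 0` this is ordinary maximum
#' likelihood.
#'
#' @param x Numeric design matrix (one column per term, no intercept column),
#'   or `NULL` for an intercept-only fit.
#' @param y Binary outcome vector with at least one case and one non-case.
#' @param penalty Non-negative L2 penalty strength (absolute, not per
#'   observation).
#' @param tol Convergence tolerance on the maximum absolute coefficient
#'   change.
#' @param max_iter Maximum Newton iterations.
#' @return A [logistic_risk_model()].
#' @export
fit_penalized <- function(x, y, penalty = 0, tol = 1e-8, max_iter = 100L) {
  y <- as.numeric(y)
  if (any(!y %in% c(0, 1))) stop("outcomes must be 0/1", call. = FALSE)
  if (sum(y) == 0 || sum(y) == length(y)) {
    stop("need at least one case and one non-case", call. = FALSE)
  }
  if (penalty < 0) stop("penalty must be non-negative", call. = FALSE)
  if (is.null(x)) x <- matrix(numeric(0), nrow = length(y), ncol = 0L)
  x <- as.matrix(x)
  if (nrow(x) != length(y)) stop("nrow(x) != length(y)", call. = FALSE)
  p <- ncol(x)
  x1 <- cbind(1, x)
  pen_diag <- c(0, rep(penalty, p))
  beta <- c(stats::qlogis(mean(y)), rep(0, p))
  ll <- .pen_loglik(beta, x1, y, penalty)
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    mu <- stats::plogis(drop(x1 %*% beta))
    w <- pmax(mu * (1 - mu), 1e-12)
    grad <- drop(crossprod(x1, y - mu)) - pen_diag * beta
    hess <- crossprod(x1, x1 * w)
    diag(hess) <- diag(hess) + pen_diag
    step <- tryCatch(solve(hess, grad), error = function(e) NULL)
    if (is.null(step)) {
      stop("singular information matrix at iteration ", iter,
           "; with penalty = 0 and separated data, refit with penalty > 0",
           call. = FALSE)
    }
    # step-halve if the penalized log-likelihood does not improve
    h <- 1
    repeat {
      cand <- beta + h * step
      ll_new <- .pen_loglik(cand, x1, y, penalty)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      h <- h / 2
      if (h < 1e-10) break
    }
    beta <- beta + h * step
    ll <- .pen_loglik(beta, x1, y, penalty)
    trace <- c(trace, ll)
    if (max(abs(h * step)) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    cond <- simpleError(paste0(
      "penalized logistic fit did not converge in ", max_iter,
      " iterations (max |coef| = ", format(max(abs(beta))),
      "); data may be separated — refit with penalty > 0"))
    cond$loglik_trace <- trace
    stop(cond)
  }
  if (penalty == 0 && p > 0 && max(abs(beta[-1L])) > 25) {
    stop("coefficients diverging under penalty = 0 (likely separation); ",
         "refit with penalty > 0", call. = FALSE)
  }
  coefs <- beta[-1L]
  names(coefs) <- colnames(x)
  logistic_risk_model(
    intercept = beta[1L], coefficients = coefs, penalty = penalty,
    meta = list(n = length(y), iterations = iter, tol = tol,
                converged = TRUE, loglik = ll))
}

#' Choose the ridge penalty by cross-validated deviance
#'
#' Stratified K-fold cross-validation over a penalty grid; the penalty with
#' the smallest mean held-out deviance wins.
#'
#' @param x,y As in [fit_penalized()].
#' @param penalties Numeric grid of candidate penalties.
#' @param nfolds Number of folds (default 10).
#' @param seed Integer seed controlling the fold assignment.
#' @return A list with `penalty` (the selected value) and `cv_deviance`
#'   (named vector of mean held-out deviance per candidate).
#' @export
cv_penalty <- function(x, y, penalties = c(0, 0.5, 1, 2, 4, 8, 16, 32),
                       nfolds = 10L, seed = 1L) {
  y <- as.numeric(y)
  x <- as.matrix(x)
  n <- length(y)
  set.seed(seed)
  folds <- integer(n)
  for (cls in c(0, 1)) {
    idx <- which(y == cls)
    folds[idx] <- sample(rep_len(seq_len(nfolds), length(idx)))
  }
  dev <- matrix(NA_real_, nrow = nfolds, ncol = length(penalties))
  for (k in seq_len(nfolds)) {
    train <- folds != k
    for (j in seq_along(penalties)) {
      fit <- fit_penalized(x[train, , drop = FALSE], y[train],
                           penalty = penalties[j])
      p_hat <- predict_prob(fit, x[!train, , drop = FALSE])
      p_hat <- pmin(pmax(p_hat, 1e-12), 1 - 1e-12)
      dev[k, j] <- -2 * sum(y[!train] * log(p_hat) +
                              (1 - y[!train]) * log(1 - p_hat))
    }
  }
  mean_dev <- colMeans(dev)
  names(mean_dev) <- format(penalties)
  list(penalty = penalties[which.min(mean_dev)], cv_deviance = mean_dev)
}

#' Linear predictor of a risk model
#'
#' @param model A [logistic_risk_model()].
#' @param x Design matrix whose columns match the model's terms exactly.
#' @return Numeric vector of log-odds.
#' @export
linear_predictor <- function(model, x) {
  stopifnot(inherits(model, "logistic_risk_model"))
  terms <- names(model$coefficients)
  if (length(terms) == 0L) {
    n <- if (is.null(x)) 1L else nrow(as.matrix(x))
    return(rep(model$intercept, n))
  }
  x <- as.matrix(x)
  missing <- setdiff(terms, colnames(x))
  extra <- setdiff(colnames(x), terms)
  if (length(missing) || length(extra)) {
    stop("design/model term mismatch; missing: [",
         paste(missing, collapse = ", "), "], extra: [",
         paste(extra, collapse = ", "), "]", call. = FALSE)
  }
  drop(model$intercept + x[, terms, drop = FALSE] %*% model$coefficients)
}

#' Predicted probabilities of a risk model
#'
#' Inverse-logit of [linear_predictor()].
#'
#' @inheritParams linear_predictor
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict_prob <- function(model, x) {
  stats::plogis(linear_predictor(model, x))
}

#' Rebuild a model on a subset of its predictors
#'
#' Refits the penalized model on the development data using only the retained
#' predictors (a genuine refit, not coefficient deletion). Dropping
#' `"maltreatment"` removes both of its dummy columns.
#'
#' @param x Development design matrix.
#' @param y Development outcomes.
#' @param drop Character vector of predictor names to remove.
#' @param penalty,tol,max_iter Passed to [fit_penalized()].
#' @return A [logistic_risk_model()] on the retained terms.
#' @export
rebuild_without_predictors <- function(x, y, drop = character(0), penalty = 0,
                                       tol = 1e-8, max_iter = 100L) {
  x <- as.matrix(x)
  drop_cols <- unlist(lapply(drop, .predictor_columns))
  unknown <- setdiff(drop_cols, colnames(x))
  if (length(unknown)) {
    stop("cannot drop unknown predictor column(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  keep <- setdiff(colnames(x), drop_cols)
  if (length(keep) == 0L) {
    warning("all predictors dropped; fitting an intercept-only model",
            call. = FALSE)
    return(fit_penalized(NULL, y, penalty = penalty, tol = tol,
                         max_iter = max_iter))
  }
  fit_penalized(x[, keep, drop = FALSE], y, penalty = penalty, tol = tol,
                max_iter = max_iter)
}

#' Write a risk model to JSON
#'
#' @param model A [logistic_risk_model()].
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @return JSON string, invisibly when written to file.
#' @export
model_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "logistic_risk_model"))
  obj <- list(intercept = model$intercept,
              terms = as.list(model$coefficients),
              penalty = model$penalty,
              meta = model$meta)
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

#' Read a risk model from JSON
#'
#' @param input A JSON string or a file path produced by [model_to_json()].
#' @return A [logistic_risk_model()].
#' @export
model_from_json <- function(input) {
  obj <- jsonlite::fromJSON(input)
  coefs <- if (length(obj$terms)) unlist(obj$terms) else numeric(0)
  logistic_risk_model(intercept = obj$intercept,
                      coefficients = coefs,
                      penalty = obj$penalty %||% 0,
                      meta = as.list(obj$meta))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
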