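# Independent oracles and small fixtures used across the suite.

# O(n^2) pairwise concordance with ties counting one-half.
auc_pairwise <- function(scores, labels) {
  cases <- scores[labels == 1]
  controls <- scores[labels == 0]
  total <- 0
  for (s in cases) {
    total <- total + sum(s > controls) + 0.5 * sum(s == controls)
  }
  total / (length(cases) * length(controls))
}

# Brute-force maximizer of the unpenalized Bernoulli log-likelihood by
# iterated grid refinement over (intercept, slopes).
grid_logistic_mle <- function(x, y, lower = -5, upper = 5, points = 11L,
                              iters = 9L) {
  x1 <- cbind(1, as.matrix(x))
  p <- ncol(x1)
  ll <- function(b) {
    eta <- drop(x1 %*% b)
    sum(y * eta - log1p(exp(eta)))
  }
  centre <- rep((lower + upper) / 2, p)
  width <- rep((upper - lower) / 2, p)
  for (it in seq_len(iters)) {
    grids <- lapply(seq_len(p), function(j) {
      seq(centre[j] - width[j], centre[j] + width[j], length.out = points)
    })
    cand <- as.matrix(expand.grid(grids))
    vals <- apply(cand, 1L, ll)
    centre <- unname(cand[which.max(vals), ])
    width <- width * 3 / (points - 1)
  }
  centre
}

# Small coded predictor frame with all seven predictors.
make_predictors <- function(n, seed = 1L) {
  set.seed(seed)
  m <- deprisk::default_marginals()
  data.frame(
    sex_female = rbinom(n, 1, m$sex_female),
    maltreatment = factor(sample(names(m$maltreatment), n, replace = TRUE,
                                 prob = m$maltreatment),
                          levels = c("none", "probable", "severe"),
                          ordered = TRUE),
    school_failure = rbinom(n, 1, m$school_failure),
    social_isolation = rbinom(n, 1, m$social_isolation),
    fights = rbinom(n, 1, m$fights),
    ran_away = rbinom(n, 1, m$ran_away),
    drug_use = rbinom(n, 1, m$drug_use))
}

# A down-scaled raw-survey spec with internally consistent flow counts.
small_raw_spec <- function(n = 300L, n_in_age = 200L, n_dep = 40L,
                           males = 80L) {
  spec <- deprisk::lagos_raw_spec()
  spec$n_followed_up <- as.integer(n)
  spec$n_in_age <- as.integer(n_in_age)
  spec$n_baseline_depressed <- as.integer(n_dep)
  spec$final_n <- as.integer(n_in_age - n_dep)
  spec$final_males <- as.integer(males)
  spec$final_females <- as.integer(spec$final_n - males)
  spec
}
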