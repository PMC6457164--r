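# Synthetic cohort generation: two-item screen, binormal latent questionnaire
# score discretised to the 0-30 ordinal scale, covariates, consent and
# missingness. All randomness flows through one set.seed() call so that a
# (config, seed) pair reproduces the cohort bit-for-bit.

#' Map latent questionnaire propensity to the ordinal score
#'
#' Fixed monotone discretisation: `clamp(round(center + scale * latent), 0, max)`.
#' @param latent numeric latent values.
#' @param config a [cohort_config()].
#' @return integer scores in `[0, 3 * item_count]`.
#' @keywords internal
discretise_score <- function(latent, config) {
  max_score <- 3L * config$item_count
  as.integer(pmin(max_score, pmax(0, round(config$score_center +
                                             config$score_scale * latent))))
}

# Additive shift of the case latent mean for given covariates (age centred at 30)
case_latent_shift <- function(config, age, ethnicity, income, education,
                              interpreter, mode) {
  ef <- config$covariate_effects
  ef$age * (age - 30) +
    ef$ethnicity[ethnicity] + ef$income[income] + ef$education[education] +
    ef$interpreter * interpreter + ef$mode * mode
}

# Split an ordinal total into item_count items of 0-3 by sampling `total` of
# the 3*item_count unit "slots" without replacement: uniform over item vectors
# with the given total respecting the per-item cap.
split_items <- function(totals, item_count) {
  slots <- rep(seq_len(item_count), each = 3L)
  t(vapply(totals, function(tt) {
    if (tt == 0L) integer(item_count)
    else tabulate(slots[sample.int(3L * item_count, tt)], nbins = item_count)
  }, integer(item_count)))
}

#' Generate a synthetic screened population
#'
#' Draws one woman per row: covariates, diagnosis flags, the two screen
#' answers (and the help question for screen-positives), questionnaire items
#' summing to the discretised latent score, a consent flag, and observation
#' flags for the gold-standard interview modules. Missing-at-random module
#' observation follows a logistic model on the questionnaire total, ethnicity
#' and employment; item missingness is MCAR.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed; defaults to `config$seed`.
#' @return a data frame of class `screening_cohort` with the canonical columns
#'   (see [write_cohort_csv()]) plus `total_score` (sum of items, `NA` when any
#'   item is missing) and `true_total` (the pre-missingness score, used only by
#'   simulation oracles).
#' @export
generate_population <- function(config, seed = config$seed) {
  if (!inherits(config, "cohort_config")) stop_config("config must be a cohort_config")
  if (is.null(seed)) stop_config("a seed is required")
  set.seed(as.integer(seed))
  n <- config$n_screen
  cd <- config$covariate_dist

  age <- stats::runif(n, cd$age_range[1], cd$age_range[2])
  ethnicity <- sample.int(length(cd$ethnicity), n, replace = TRUE, prob = cd$ethnicity)
  income <- sample.int(length(cd$income), n, replace = TRUE, prob = cd$income)
  education <- sample.int(length(cd$education), n, replace = TRUE, prob = cd$education)
  employment <- stats::rbinom(n, 1, cd$employment)
  interpreter <- stats::rbinom(n, 1, cd$interpreter)
  mode <- stats::rbinom(n, 1, cd$mode)

  pv <- config$prevalence
  dx_depression <- stats::rbinom(n, 1, pv[["depression"]])
  dx_anxiety <- stats::rbinom(n, 1, pv[["anxiety"]])
  comp <- pv[setdiff(names(pv), "any_disorder")]
  p_resid <- 1 - (1 - pv[["any_disorder"]]) / prod(1 - comp)
  dx_other <- stats::rbinom(n, 1, p_resid)
  dx_any <- as.integer(dx_depression | dx_anxiety | dx_other)

  p_pos <- ifelse(dx_depression == 1, config$screen_sens, 1 - config$screen_spec)
  positive <- stats::rbinom(n, 1, p_pos) == 1
  p_both <- ifelse(dx_depression == 1, config$p_both_given_pos[["case"]],
                   config$p_both_given_pos[["noncase"]])
  both <- positive & stats::rbinom(n, 1, p_both) == 1
  # among single-question positives, which question was endorsed
  q1_only <- positive & !both & stats::rbinom(n, 1, 0.5) == 1
  screen_q1 <- as.integer(both | q1_only)
  screen_q2 <- as.integer(both | (positive & !both & !q1_only))

  p_h <- ifelse(dx_depression == 1, config$p_help[["case"]], config$p_help[["noncase"]])
  help_q <- ifelse(positive, stats::rbinom(n, 1, p_h), NA_integer_)

  shift <- case_latent_shift(config, age, ethnicity, income, education,
                             interpreter, mode)
  latent <- ifelse(dx_depression == 1,
                   stats::rnorm(n, config$mu1 + shift, config$sigma1),
                   stats::rnorm(n, 0, 1))
  true_total <- discretise_score(latent, config)
  items <- split_items(true_total, config$item_count)
  colnames(items) <- paste0("item_", seq_len(config$item_count))
  if (config$item_missing > 0) {
    miss <- matrix(stats::runif(n * config$item_count) < config$item_missing,
                   nrow = n)
    items[miss] <- NA_integer_
  }

  consented <- stats::rbinom(n, 1, config$consent_rate) == 1

  mm <- config$module_missing_coef
  eth_eff <- c(0, mm[c("eth2", "eth3", "eth4", "eth5")])[ethnicity]
  lin <- mm[["intercept"]] + mm[["total_score"]] * true_total +
    mm[["employment"]] * employment + eth_eff
  p_obs <- stats::plogis(lin)
  module_observed_depression <- stats::rbinom(n, 1, p_obs) == 1
  module_observed_any <- stats::rbinom(n, 1, p_obs) == 1

  out <- data.frame(
    id = sprintf("w%06d", seq_len(n)),
    age = age,
    ethnicity = paste0("eth", ethnicity),
    income = paste0("inc", income),
    education = paste0("edu", education),
    employment = employment,
    interpreter = interpreter,
    mode = mode,
    dx_depression = dx_depression,
    dx_anxiety = dx_anxiety,
    dx_any = dx_any,
    screen_q1 = screen_q1,
    screen_q2 = screen_q2,
    help_q = help_q,
    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(items))
  out$consented <- consented
  out$stratum <- ifelse(positive, "positive", "negative")
  out$module_observed_depression <- module_observed_depression
  out$module_observed_any <- module_observed_any
  out$total_score <- rowSums(items)   # NA when any item missing
  out$true_total <- true_total
  class(out) <- c("screening_cohort", "data.frame")
  out
}

#' Recompute the questionnaire total from item columns
#'
#' @param records a cohort data frame.
#' @param item_count number of item columns.
#' @return `records` with `total_score` replaced by the row sum of the items
#'   (`NA` when any item is missing).
#' @export
with_total_score <- function(records, item_count = 10L) {
  cols <- paste0("item_", seq_len(item_count))
  records$total_score <- rowSums(records[cols])
  records
}

#' Closed-form ROC truth of the generating binormal model
#'
#' For controls N(0,1) and cases N(mu1 + shift, sigma1) the ROC curve is
#' `ROC(t) = pnorm(a0 + a1 * qnorm(t))` with `a0 = (mu1 + shift) / sigma1` and
#' `a1 = 1 / sigma1`, and `AUC = pnorm((mu1 + shift) / sqrt(1 + sigma1^2))`.
#' Exact; no simulation. Refers to the latent (pre-discretisation) score.
#'
#' @param config a [cohort_config()].
#' @param shift additive case-mean shift at which to evaluate (default 0 =
#'   reference covariates).
#' @param t_grid grid of false-positive rates.
#' @return list with `auc`, `alpha0`, `alpha1`, and a data frame `curve` of
#'   `(t, roc)`.
#' @export
empirical_roc_truth <- function(config, shift = 0,
                                t_grid = seq(0.01, 0.99, by = 0.01)) {
  if (!inherits(config, "cohort_config")) stop_config("config must be a cohort_config")
  m <- config$mu1 + shift
  a0 <- m / config$sigma1
  a1 <- 1 / config$sigma1
  list(auc = stats::pnorm(m / sqrt(1 + config$sigma1^2)),
       alpha0 = a0, alpha1 = a1,
       curve = data.frame(t = t_grid, roc = stats::pnorm(a0 + a1 * stats::qnorm(t_grid))))
}

#' Simulate a case-control set of discretised questionnaire scores
#'
#' Lower-level generator sharing the latent-score machinery of
#' [generate_population()]: controls N(0,1), cases N(mu1 + beta_age * (age-30),
#' sigma1), both mapped through the same monotone discretisation. Used for
#' parameter-recovery experiments for the ROC regression.
#'
#' @param n_cases,n_controls group sizes.
#' @param mu1,sigma1 case latent mean (at age 30) and SD.
#' @param beta_age slope of the case latent mean per year of age.
#' @param config a [cohort_config()] supplying the discretisation map.
#' @param seed integer seed.
#' @param discretise if `FALSE`, return the latent scores themselves.
#' @return data frame with `status` (1 = case), `age`, `score`, `weight` (all 1).
#' @export
simulate_case_control <- function(n_cases, n_controls, mu1 = 1.78, sigma1 = 1,
                                  beta_age = 0, config = cohort_config(),
                                  seed, discretise = TRUE) {
  set.seed(as.integer(seed))
  n <- n_cases + n_controls
  status <- rep(c(1L, 0L), c(n_cases, n_controls))
  age <- stats::runif(n, 16, 45)
  latent <- ifelse(status == 1L,
                   stats::rnorm(n, mu1 + beta_age * (age - 30), sigma1),
                   stats::rnorm(n, 0, 1))
  score <- if (discretise) discretise_score(latent, config) else latent
  data.frame(status = status, age = age, score = score, weight = 1)
}
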