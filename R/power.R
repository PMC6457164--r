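# Design calculations for a planned two-phase screening validation study:
# closed-form expected stratum yields and case counts, simulated bootstrap CI
# widths for the weighted accuracy estimators, and simulated power of a
# cases-only comparison of instrument sensitivities.

#' Configuration of a planned two-phase design
#'
#' Defaults are a design of 6000 women screened, 9% depression prevalence, a
#' screen with sensitivity 0.95 and specificity 0.89, 66% consent, and
#' verification sampling fractions 0.54 (screen-positive) and 0.06
#' (screen-negative); the instrument under evaluation is assumed to have
#' sensitivity 0.80 and specificity 0.71, compared for power against a
#' reference sensitivity of 0.65.
#'
#' @param n_screen women screened.
#' @param prevalence prevalence of the reference diagnosis.
#' @param screen_sens,screen_spec screen operating characteristics.
#' @param consent_rate consent probability among those invited.
#' @param sample_fraction_pos,sample_fraction_neg verification sampling
#'   fractions per stratum.
#' @param n_interview_pos,n_interview_neg optional planned interviewed counts;
#'   when given they override the fraction-derived expected counts (a protocol
#'   often states whole-number targets whose printed fractions are rounded).
#' @param assumed_index_sens,assumed_index_spec assumed operating
#'   characteristics of the instrument under evaluation.
#' @param comparator_sens reference sensitivity for the power comparison.
#' @param alpha two-sided significance level.
#' @param replicates simulation replicates (>= 200 for reported power).
#' @param bootstrap_B bootstrap replicates inside each simulation replicate.
#' @param seed optional default seed.
#' @return a `design_config`.
#' @export
design_config <- function(n_screen = 6000, prevalence = 0.09,
                          screen_sens = 0.95, screen_spec = 0.89,
                          consent_rate = 0.66,
                          sample_fraction_pos = 0.54,
                          sample_fraction_neg = 0.06,
                          n_interview_pos = NULL, n_interview_neg = NULL,
                          assumed_index_sens = 0.80,
                          assumed_index_spec = 0.71,
                          comparator_sens = 0.65,
                          alpha = 0.05, replicates = 200, bootstrap_B = 500,
                          seed = NULL) {
  for (nm in c("prevalence", "screen_sens", "screen_spec", "consent_rate",
               "sample_fraction_pos", "sample_fraction_neg",
               "assumed_index_sens", "assumed_index_spec", "comparator_sens",
               "alpha"))
    check_prob(get(nm), nm)
  if (n_screen < 1) stop_config("n_screen must be >= 1")
  rm(nm)
  structure(as.list(environment()), class = "design_config")
}

# Bayes conditionals of disease given screen result
screen_conditionals <- function(config) {
  p <- config$prevalence
  p_pos <- p * config$screen_sens + (1 - p) * (1 - config$screen_spec)
  list(p_pos = p_pos,
       p_d_pos = p * config$screen_sens / p_pos,
       p_d_neg = p * (1 - config$screen_sens) / (1 - p_pos))
}

#' Expected yield of a two-phase design (closed form)
#'
#' Expected interviewed counts per stratum,
#' `n_h = n_screen * P(stratum) * consent * fraction_h` (or the planned
#' counts when the config states them), and the expected number of diseased
#' interviewees `n_pos * P(D | screen+) + n_neg * P(D | screen-)`. Exact; no
#' simulation.
#'
#' @param config a [design_config()].
#' @return list: `expected_n_pos`, `expected_n_neg`, `expected_cases`
#'   (unrounded), plus `rounded` (all three rounded to whole women) and the
#'   screen conditionals used.
#' @export
expected_yield <- function(config) {
  sc <- screen_conditionals(config)
  n_pos <- config$n_interview_pos %||%
    (config$n_screen * sc$p_pos * config$consent_rate * config$sample_fraction_pos)
  n_neg <- config$n_interview_neg %||%
    (config$n_screen * (1 - sc$p_pos) * config$consent_rate * config$sample_fraction_neg)
  cases <- n_pos * sc$p_d_pos + n_neg * sc$p_d_neg
  list(expected_n_pos = n_pos, expected_n_neg = n_neg,
       expected_cases = cases,
       rounded = c(n_pos = round_half_up(n_pos), n_neg = round_half_up(n_neg),
                   cases = round_half_up(cases)),
       conditionals = sc)
}

# one simulated two-phase study at the design parameters: returns an
# interviewed record table with stratum, weights, disease and index test
simulate_design_study <- function(config) {
  sc <- screen_conditionals(config)
  n_pos_frame <- stats::rbinom(1, config$n_screen, sc$p_pos)
  n_neg_frame <- config$n_screen - n_pos_frame
  n_int_pos <- stats::rbinom(1, n_pos_frame,
                             config$sample_fraction_pos * config$consent_rate)
  n_int_neg <- stats::rbinom(1, n_neg_frame,
                             config$sample_fraction_neg * config$consent_rate)
  if (n_int_pos == 0 || n_int_neg == 0) return(NULL)
  stratum <- rep(c("positive", "negative"), c(n_int_pos, n_int_neg))
  p_d <- ifelse(stratum == "positive", sc$p_d_pos, sc$p_d_neg)
  d <- stats::rbinom(length(p_d), 1, p_d)
  p_t <- ifelse(d == 1, config$assumed_index_sens, 1 - config$assumed_index_spec)
  test_pos <- stats::rbinom(length(p_t), 1, p_t)
  w <- ifelse(stratum == "positive", n_pos_frame / n_int_pos,
              n_neg_frame / n_int_neg)
  data.frame(stratum = stratum, dx = d, test_pos = test_pos, weight = w)
}

weighted_se_sp <- function(r) {
  se <- sum(r$weight[r$dx == 1 & r$test_pos == 1]) / sum(r$weight[r$dx == 1])
  sp <- sum(r$weight[r$dx == 0 & r$test_pos == 0]) / sum(r$weight[r$dx == 0])
  c(sensitivity = se, specificity = sp)
}

#' Simulated bootstrap CI widths of the weighted accuracy estimators
#'
#' Per replicate: draw a screened population at the design parameters, apply
#' the two-phase sampling and consent, mark index-test results at the assumed
#' sensitivity/specificity, compute the design-weighted Se and Sp, and a
#' stratified percentile bootstrap CI for each; report mean widths with
#' Monte-Carlo standard errors.
#'
#' @param config a [design_config()].
#' @param seed integer seed.
#' @return list: `ci_width_sens`, `ci_width_spec`, their `mc_se`, replicate
#'   counts and the number of dropped (caseless) replicates. Errors if more
#'   than 5% of replicates are dropped.
#' @export
simulate_ci_width <- function(config, seed = config$seed) {
  if (config$bootstrap_B < 200) stop_config("bootstrap_B must be >= 200")
  set.seed(as.integer(seed))
  widths <- matrix(NA_real_, config$replicates, 2)
  dropped <- 0
  for (r in seq_len(config$replicates)) {
    study <- simulate_design_study(config)
    est <- if (is.null(study)) NULL else tryCatch(weighted_se_sp(study),
                                                  error = function(e) NULL)
    if (is.null(study) || is.null(est) || anyNA(est) ||
        sum(study$dx) == 0 || sum(study$dx == 0) == 0) {
      dropped <- dropped + 1
      next
    }
    ci <- bootstrap_ci(study, weighted_se_sp, B = config$bootstrap_B,
                       seed = sample.int(.Machine$integer.max, 1),
                       strata = study$stratum)
    widths[r, ] <- ci$high - ci$low
  }
  if (dropped > 0.05 * config$replicates)
    stop("more than 5% of replicates yielded no cases (", dropped, " dropped)")
  ok <- stats::complete.cases(widths)
  list(ci_width_sens = mean(widths[ok, 1]), ci_width_spec = mean(widths[ok, 2]),
       mc_se_sens = mc_se(widths[ok, 1]), mc_se_spec = mc_se(widths[ok, 2]),
       replicates = sum(ok), dropped = dropped)
}

# rejection set of the exact two-sided binomial test of p0 at level alpha
binom_rejection_set <- function(n, p0, alpha) {
  pv <- vapply(0:n, function(k) stats::binom.test(k, n, p0)$p.value, numeric(1))
  which(pv < alpha) - 1L
}

#' Simulated power of the sensitivity comparison
#'
#' `one_sample_vs_reference` (default): per replicate, the number of index-test
#' positives among `n_cases` diseased women is drawn at the assumed
#' sensitivity and the exact two-sided binomial test of the comparator
#' sensitivity is applied; power is the rejection fraction. The cases-only
#' one-sample test is a conservative reading of a planned comparison of two
#' instruments' sensitivities. `two_sample_independent` draws both
#' instruments' positives independently and applies a chi-square test of the
#' two proportions.
#'
#' @param config a [design_config()].
#' @param test_spec `"one_sample_vs_reference"` or `"two_sample_independent"`.
#' @param n_cases diseased sample size; default the rounded expected case
#'   count from [expected_yield()].
#' @param replicates simulation replicates (default `config$replicates`; use
#'   >= 5000 for a reported power).
#' @param seed integer seed.
#' @return a `power_report`: `power`, `mc_se`, `replicates`, `n_cases`, test
#'   description.
#' @export
simulate_power <- function(config,
                           test_spec = c("one_sample_vs_reference",
                                         "two_sample_independent"),
                           n_cases = NULL, replicates = config$replicates,
                           seed = config$seed) {
  test_spec <- match.arg(test_spec)
  if (replicates < 200) stop_config("replicates must be >= 200")
  n_cases <- as.integer(n_cases %||% expected_yield(config)$rounded[["cases"]])
  set.seed(as.integer(seed))
  if (test_spec == "one_sample_vs_reference") {
    rej <- binom_rejection_set(n_cases, config$comparator_sens, config$alpha)
    x <- stats::rbinom(replicates, n_cases, config$assumed_index_sens)
    hit <- x %in% rej
  } else {
    x1 <- stats::rbinom(replicates, n_cases, config$assumed_index_sens)
    x2 <- stats::rbinom(replicates, n_cases, config$comparator_sens)
    hit <- vapply(seq_len(replicates), function(i)
      stats::prop.test(c(x1[i], x2[i]), c(n_cases, n_cases))$p.value <
        config$alpha, logical(1))
  }
  p <- mean(hit)
  structure(list(power = p, mc_se = sqrt(p * (1 - p) / replicates),
                 replicates = replicates, n_cases = n_cases,
                 test = test_spec, alpha = config$alpha,
                 assumed_sens = config$assumed_index_sens,
                 comparator_sens = config$comparator_sens),
            class = "power_report")
}

#' @export
print.power_report <- function(x, ...) {
  cat(sprintf("<power_report> %s: Se %.2f vs %.2f, n = %d cases, alpha = %g\n",
              x$test, x$assumed_sens, x$comparator_sens, x$n_cases, x$alpha))
  cat(sprintf("  power = %.3f (MC SE %.4f, %d replicates)\n",
              x$power, x$mc_se, x$replicates))
  invisible(x)
}
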