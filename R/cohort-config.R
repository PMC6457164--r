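#' Configuration of a synthetic screened cohort
#'
#' Describes the generative model for a screened antenatal population: diagnosis
#' prevalences, the operating characteristics of a two-item binary screen
#' (positive = yes to either question), a binormal latent model for a 10-item
#' 0--30 questionnaire score, covariate effects on case discrimination, consent,
#' and missingness of questionnaire items and gold-standard interview modules.
#'
#' The defaults describe an inner-city antenatal booking population of 9963
#' women: depression prevalence 11%, anxiety 15%, any disorder 27%; a screen
#' with sensitivity 0.41 and specificity 0.945 for depression (giving a
#' positivity rate near 9%); and a latent score model in which the cut-off
#' 12/13 has sensitivity about 0.59 and specificity about 0.94 for depression,
#' with binormal AUC about 0.89.
#'
#' @param n_screen number of women screened.
#' @param prevalence named probabilities; must contain `depression`, `anxiety`
#'   and `any_disorder`; `any_disorder` is realised as the union of the named
#'   component disorders plus an independent residual category, so it must be
#'   at least `1 - prod(1 - components)`.
#' @param screen_sens,screen_spec probability that the screen is positive given
#'   depression, and negative given no depression.
#' @param item_count number of questionnaire items (each scored 0--3).
#' @param mu1,sigma1 latent case mean and SD at reference covariates; controls
#'   are standard normal.
#' @param score_center,score_scale affine map from the latent scale to the
#'   ordinal score: `score = clamp(round(center + scale * latent), 0, 3 * item_count)`.
#' @param covariate_effects list of additive shifts of the case latent mean:
#'   `age` (slope per year, centred at 30), `ethnicity` (length 5), `income`
#'   (length 5), `education` (length 3), `interpreter`, `mode` (scalars).
#' @param covariate_dist list giving the covariate distributions: multinomial
#'   probabilities for `ethnicity`, `income`, `education`; Bernoulli
#'   probabilities for `employment`, `interpreter`, `mode`; `age_range`.
#' @param p_both_given_pos named probabilities (`case`, `noncase`) that a
#'   screen-positive answered yes to both questions rather than one.
#' @param p_help named probabilities (`case`, `noncase`) of answering yes to
#'   the additional help question, asked only of screen-positives.
#' @param consent_rate probability of consenting to interview given invited.
#' @param item_missing per-item MCAR missingness probability.
#' @param module_missing_coef logistic coefficients for the probability that a
#'   gold-standard module is *observed*: named vector with `intercept`,
#'   `total_score`, `employment`, and `eth2`..`eth5` contrasts.
#' @param seed optional default seed used when [generate_population()] is
#'   called without one.
#'
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_screen = 9963,
                          prevalence = c(depression = 0.11, anxiety = 0.15,
                                         any_disorder = 0.27),
                          screen_sens = 0.41,
                          screen_spec = 0.945,
                          item_count = 10L,
                          mu1 = 1.78,
                          sigma1 = 1,
                          score_center = 5.5,
                          score_scale = 4.5,
                          covariate_effects = list(
                            age = -0.03,
                            ethnicity = c(0, 0, 0, 0, 0),
                            income = c(0, 0, 0, 0, 0),
                            education = c(0, 0, 0),
                            interpreter = 0.3,
                            mode = 0),
                          covariate_dist = list(
                            ethnicity = c(0.35, 0.25, 0.20, 0.12, 0.08),
                            income = c(0.25, 0.25, 0.20, 0.20, 0.10),
                            education = c(0.30, 0.40, 0.30),
                            employment = 0.60,
                            interpreter = 0.07,
                            mode = 0.17,
                            age_range = c(16, 45)),
                          p_both_given_pos = c(case = 0.61, noncase = 0.35),
                          p_help = c(case = 0.20, noncase = 0.18),
                          consent_rate = 0.34,
                          item_missing = 0.005,
                          module_missing_coef = c(intercept = 3.5,
                                                  total_score = -0.05,
                                                  employment = 0.4,
                                                  eth2 = 0, eth3 = 0,
                                                  eth4 = -0.3, eth5 = -0.3),
                          seed = NULL) {
  if (!is.numeric(n_screen) || length(n_screen) != 1 || n_screen < 1)
    stop_config("n_screen must be a single count >= 1")
  n_screen <- as.integer(n_screen)
  needed <- c("depression", "anxiety", "any_disorder")
  if (!all(needed %in% names(prevalence)))
    stop_config("prevalence must name ", paste(needed, collapse = ", "))
  check_prob(prevalence, "prevalence")
  comp <- prevalence[setdiff(names(prevalence), "any_disorder")]
  if (prevalence[["any_disorder"]] < max(comp))
    stop_config("any_disorder prevalence must be >= every component prevalence")
  min_union <- 1 - prod(1 - comp)
  if (prevalence[["any_disorder"]] < min_union - 1e-12)
    stop_config("any_disorder prevalence ", prevalence[["any_disorder"]],
                " is below the union of independent components (",
                signif(min_union, 4), "); components cannot be independent")
  check_prob(screen_sens, "screen_sens")
  check_prob(screen_spec, "screen_spec")
  check_prob(consent_rate, "consent_rate")
  check_prob(item_missing, "item_missing")
  check_prob(p_both_given_pos, "p_both_given_pos")
  check_prob(p_help, "p_help")
  if (!is.numeric(item_count) || length(item_count) != 1 || item_count <= 0)
    stop_config("item_count must be a positive integer")
  item_count <- as.integer(item_count)
  if (!is.numeric(sigma1) || sigma1 <= 0) stop_config("sigma1 must be > 0")
  for (nm in c("ethnicity", "income", "education")) {
    p <- covariate_dist[[nm]]
    check_prob(p, paste0("covariate_dist$", nm))
    if (abs(sum(p) - 1) > 1e-8)
      stop_config("covariate_dist$", nm, " must sum to 1")
  }
  stopifnot(length(covariate_effects$ethnicity) == length(covariate_dist$ethnicity),
            length(covariate_effects$income) == length(covariate_dist$income),
            length(covariate_effects$education) == length(covariate_dist$education))

  structure(list(n_screen = n_screen, prevalence = prevalence,
                 screen_sens = screen_sens, screen_spec = screen_spec,
                 item_count = item_count, mu1 = mu1, sigma1 = sigma1,
                 score_center = score_center, score_scale = score_scale,
                 covariate_effects = covariate_effects,
                 covariate_dist = covariate_dist,
                 p_both_given_pos = p_both_given_pos, p_help = p_help,
                 consent_rate = consent_rate, item_missing = item_missing,
                 module_missing_coef = module_missing_coef, seed = seed),
            class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat("  n_screen:", x$n_screen, "\n")
  cat("  prevalence:", paste(names(x$prevalence), signif(x$prevalence, 3),
                             sep = "=", collapse = ", "), "\n")
  cat("  screen: Se", x$screen_sens, "/ Sp", x$screen_spec, "\n")
  cat("  latent: mu1", x$mu1, "sigma1", x$sigma1,
      "-> binormal AUC", signif(stats::pnorm(x$mu1 / sqrt(1 + x$sigma1^2)), 3), "\n")
  invisible(x)
}
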