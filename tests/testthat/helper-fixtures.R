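# Small in-code fixtures shared across test files.

# A cohort config with no missingness of any kind (items always observed,
# modules always completed) for checks that need fully observed data.
config_no_missing <- function(...) {
  cohort_config(item_missing = 0,
                module_missing_coef = c(intercept = 30, total_score = 0,
                                        employment = 0, eth2 = 0, eth3 = 0,
                                        eth4 = 0, eth5 = 0),
                ...)
}

# interviewed two-phase sample with design weights attached
sampled_cohort <- function(config = cohort_config(), seed = 11,
                           schedule = data.frame(start = 1, k = 6)) {
  pop <- generate_population(config, seed = seed)
  pop <- draw_sample(pop, schedule, seed = seed + 1)
  w <- compute_weights(pop)
  list(population = pop,
       interviewed = apply_design_weights(pop[pop$interviewed, ], w),
       weights = w)
}

# the published raw counts for the either-question rule against depression:
# 130 of 287 screen-positive and 17 of 258 screen-negative women diseased,
# frame 906 screen-positive / 9057 screen-negative
printed_depression_records <- function() {
  records_from_counts(data.frame(
    stratum = rep(c("positive", "negative"), each = 2),
    screen_q1 = c(1, 1, 0, 0), screen_q2 = 0,
    help_q = NA_integer_, total_score = NA_real_,
    dx_depression = c(1, 0, 1, 0),
    n = c(130, 157, 17, 241)))
}

printed_frame <- c(positive = 906, negative = 9057)

# small random weighted record table for brute-force comparisons
random_weighted_records <- function(n, seed) {
  set.seed(seed)
  q1 <- sample(0:1, n, replace = TRUE)
  q2 <- sample(0:1, n, replace = TRUE)
  data.frame(
    stratum = ifelse(q1 == 1 | q2 == 1, "positive", "negative"),
    screen_q1 = q1, screen_q2 = q2,
    help_q = ifelse(q1 == 1 | q2 == 1, sample(0:1, n, replace = TRUE),
                    NA_integer_),
    total_score = sample(0:30, n, replace = TRUE),
    dx_depression = sample(0:1, n, replace = TRUE),
    module_observed_depression = TRUE,
    design_weight = runif(n, 0.5, 40))
}
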