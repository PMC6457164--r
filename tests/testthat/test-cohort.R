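test_that("generation is deterministic given config and seed", {
  cfg <- cohort_config(n_screen = 400)
  a <- generate_population(cfg, seed = 5)
  b <- generate_population(cfg, seed = 5)
  expect_identical(a, b)
  c <- generate_population(cfg, seed = 6)
  expect_false(identical(a, c))
})

test_that("degenerate prevalence yields no flagged records", {
  cfg <- cohort_config(n_screen = 500,
                       prevalence = c(depression = 0, anxiety = 0.1,
                                      any_disorder = 0.15))
  pop <- generate_population(cfg, seed = 2)
  expect_equal(sum(pop$dx_depression), 0)
})

test_that("screen operating characteristics calibrate at the design values", {
  # generator run at assumed screen Se 0.95 / Sp 0.89, prevalence 0.09
  cfg <- config_no_missing(n_screen = 50000,
                           prevalence = c(depression = 0.09, anxiety = 0.12,
                                          any_disorder = 0.25),
                           screen_sens = 0.95, screen_spec = 0.89)
  pop <- generate_population(cfg, seed = 101)
  case <- pop$dx_depression == 1
  se_hat <- mean(pop$stratum[case] == "positive")
  sp_hat <- mean(pop$stratum[!case] == "negative")
  se_tol <- 3 * sqrt(0.95 * 0.05 / sum(case))
  sp_tol <- 3 * sqrt(0.89 * 0.11 / sum(!case))
  expect_lt(abs(se_hat - 0.95), se_tol)
  expect_lt(abs(sp_hat - 0.89), sp_tol)
  # marginal prevalence calibration
  expect_lt(abs(mean(case) - 0.09), 3 * sqrt(0.09 * 0.91 / nrow(pop)))
  expect_lt(abs(mean(pop$dx_any) - 0.25), 3 * sqrt(0.25 * 0.75 / nrow(pop)))
})

test_that("structural record invariants hold", {
  pop <- generate_population(cohort_config(n_screen = 3000), seed = 7)
  pos <- pop$screen_q1 == 1 | pop$screen_q2 == 1
  expect_identical(pop$stratum == "positive", pos)
  expect_true(all(is.na(pop$help_q[!pos])))
  expect_true(all(!is.na(pop$help_q[pos])))
  expect_true(all(pop$true_total >= 0 & pop$true_total <= 30))
  items <- as.matrix(pop[paste0("item_", 1:10)])
  expect_true(all(is.na(items) | (items >= 0 & items <= 3)))
  # items sum to the discretised latent total where fully observed
  full <- !apply(items, 1, anyNA)
  expect_equal(rowSums(items[full, ]), pop$true_total[full])
})

test_that("discretisation is monotone and bounded", {
  cfg <- cohort_config()
  x <- sort(rnorm(500, 0, 3))
  s <- twophasedx:::discretise_score(x, cfg)
  expect_true(all(diff(s) >= 0))
  expect_true(all(s >= 0 & s <= 30))
})

test_that("zero covariate effects make the case score model covariate-free", {
  cfg <- cohort_config(covariate_effects = list(
    age = 0, ethnicity = rep(0, 5), income = rep(0, 5), education = rep(0, 3),
    interpreter = 0, mode = 0))
  # the generating distribution itself is checked: the latent case mean shift
  # is identically zero for arbitrary covariate profiles
  shift <- twophasedx:::case_latent_shift(cfg, age = c(16, 30, 45),
                                          ethnicity = c(1, 3, 5),
                                          income = c(1, 5, 2),
                                          education = c(1, 2, 3),
                                          interpreter = c(0, 1, 0),
                                          mode = c(1, 0, 1))
  expect_identical(shift, c(0, 0, 0))
})

test_that("closed-form ROC truth matches binormal formulas", {
  expect_equal(empirical_roc_truth(cohort_config(mu1 = 0, sigma1 = 1))$auc, 0.5)
  expect_gt(empirical_roc_truth(cohort_config(mu1 = 20, sigma1 = 1))$auc, 0.9999)
  tr <- empirical_roc_truth(cohort_config(mu1 = 1, sigma1 = 1))
  expect_equal(tr$auc, pnorm(1 / sqrt(2)), tolerance = 1e-12)
  # cross-check AUC against numerical integration of the ROC curve
  f <- function(t) pnorm(tr$alpha0 + tr$alpha1 * qnorm(t))
  expect_equal(tr$auc, integrate(f, 0, 1, rel.tol = 1e-10)$value,
               tolerance = 1e-6)
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(screen_sens = 1.2), "0,1")
  expect_error(cohort_config(n_screen = 0), "n_screen")
  expect_error(cohort_config(item_count = 0), "item_count")
  expect_error(cohort_config(sigma1 = -1), "sigma1")
  expect_error(cohort_config(prevalence = c(depression = 0.3, anxiety = 0.1,
                                            any_disorder = 0.2)),
               "any_disorder")
})
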