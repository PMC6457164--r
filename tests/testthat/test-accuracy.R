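test_that("weighted cells equal brute-force per-record weight sums", {
  rec <- random_weighted_records(40, seed = 12)
  for (tt in list(test_definition("either_positive"),
                  test_definition("both_positive"),
                  test_definition("score_threshold", 15))) {
    tab <- weighted_2x2(rec, tt, "depression")
    pos <- evaluate_test(rec, tt)
    dx <- rec$dx_depression == 1
    expect_equal(tab$tp, sum(rec$design_weight[pos & dx]), tolerance = 1e-12)
    expect_equal(tab$fp, sum(rec$design_weight[pos & !dx]), tolerance = 1e-12)
    expect_equal(tab$fn, sum(rec$design_weight[!pos & dx]), tolerance = 1e-12)
    expect_equal(tab$tn, sum(rec$design_weight[!pos & !dx]), tolerance = 1e-12)
    expect_equal(tab$raw_tp + tab$raw_fp + tab$raw_fn + tab$raw_tn, 40)
  }
})

test_that("unit weights reduce weighted cells to raw counts", {
  rec <- random_weighted_records(60, seed = 3)
  rec$design_weight <- 1
  tab <- weighted_2x2(rec, test_definition("either_positive"), "depression")
  expect_identical(tab$tp, as.numeric(tab$raw_tp))
  expect_identical(tab$tn, as.numeric(tab$raw_tn))
})

test_that("Bayes consistency holds exactly on the weighted table", {
  rec <- random_weighted_records(80, seed = 8)
  a <- accuracy_from_2x2(weighted_2x2(rec, test_definition("score_threshold", 12),
                                      "depression"))
  pi <- a$prevalence
  ppv_bayes <- a$sensitivity * pi /
    (a$sensitivity * pi + (1 - a$specificity) * (1 - pi))
  expect_equal(a$ppv, ppv_bayes, tolerance = 1e-12)
  # post-test odds identity: ppv/(1-ppv) = LR+ x pre-test odds
  expect_equal(a$ppv / (1 - a$ppv), a$lr_pos * pi / (1 - pi), tolerance = 1e-12)
})

test_that("a perfect test yields all-ones accuracy", {
  rec <- random_weighted_records(50, seed = 5)
  rec$total_score <- ifelse(rec$dx_depression == 1, 25, 3)
  a <- accuracy_from_2x2(weighted_2x2(rec, test_definition("score_threshold", 13),
                                      "depression"))
  expect_equal(c(a$sensitivity, a$specificity, a$ppv, a$npv), rep(1, 4))
  expect_true(a$lr_pos_infinite)
  expect_true(is.infinite(a$lr_pos))
})

test_that("all estimates are invariant to rescaling the weights", {
  rec <- random_weighted_records(70, seed = 9)
  a <- accuracy_from_2x2(weighted_2x2(rec, test_definition("either_positive"),
                                      "depression"))
  rec2 <- rec
  rec2$design_weight <- rec2$design_weight * 17.3
  b <- accuracy_from_2x2(weighted_2x2(rec2, test_definition("either_positive"),
                                      "depression"))
  for (m in c("sensitivity", "specificity", "ppv", "npv", "lr_pos", "lr_neg",
              "prevalence"))
    expect_equal(a[[m]], b[[m]], tolerance = 1e-12, info = m)
})

test_that("empty disease margins raise errors naming the margin", {
  rec <- random_weighted_records(30, seed = 2)
  rec$dx_depression <- 1
  tab <- weighted_2x2(rec, test_definition("either_positive"), "depression")
  expect_error(accuracy_from_2x2(tab), "non-diseased margin")
  rec$dx_depression <- 0
  tab <- weighted_2x2(rec, test_definition("either_positive"), "depression")
  expect_error(accuracy_from_2x2(tab), "diseased margin")
})

test_that("records with unevaluable rules are excluded and counted", {
  rec <- random_weighted_records(50, seed = 14)
  rec$help_q[rec$stratum == "positive"][1:3] <- NA
  n_pos_na <- 3
  tab <- weighted_2x2(rec, test_definition("either_plus_help"), "depression")
  expect_equal(tab$n_excluded, n_pos_na)
  rec$total_score[1:5] <- NA
  tab <- weighted_2x2(rec, test_definition("score_threshold", 10), "depression")
  expect_equal(tab$n_excluded, 5)
})

test_that("sensitivity and specificity do not depend on prevalence", {
  # same conditional error rates at two prevalences; weighted estimates agree
  mean_se <- function(prev, seed) {
    cfg <- design_config(n_screen = 4000, prevalence = prev, seed = seed)
    set.seed(seed)
    reps <- replicate(60, {
      s <- twophasedx:::simulate_design_study(cfg)
      twophasedx:::weighted_se_sp(s)
    })
    rowMeans(reps, na.rm = TRUE)
  }
  a <- mean_se(0.10, 41)
  b <- mean_se(0.30, 42)
  expect_lt(abs(a[["sensitivity"]] - b[["sensitivity"]]), 0.02)
  expect_lt(abs(a[["specificity"]] - b[["specificity"]]), 0.02)
})

test_that("weighted prevalence behaves as a Horvitz-Thompson ratio", {
  rec <- random_weighted_records(100, seed = 20)
  rec$dx_depression <- 1
  p <- prevalence_estimates(rec, "depression", B = 0)
  expect_equal(p$prevalence, 1)
  rec <- random_weighted_records(100, seed = 21)
  p1 <- prevalence_estimates(rec, "depression", B = 0)$prevalence
  rec$design_weight <- rec$design_weight * 10
  p2 <- prevalence_estimates(rec, "depression", B = 0)$prevalence
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("two-phase weighted prevalence is unbiased for the population value", {
  cfg <- config_no_missing(
    n_screen = 5000, consent_rate = 1,
    prevalence = c(depression = 0.11, anxiety = 0.15, any_disorder = 0.27))
  pop <- generate_population(cfg, seed = 55)
  truth <- mean(pop$dx_any)
  ests <- vapply(1:200, function(r) {
    s <- draw_sample(pop, data.frame(start = 1, k = 5), seed = 3000 + r)
    int <- apply_design_weights(s[s$interviewed, ], compute_weights(s))
    prevalence_estimates(int, "any", B = 0)$prevalence
  }, numeric(1))
  expect_lt(abs(mean(ests) - truth), 3 * sd(ests) / sqrt(length(ests)))
})
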