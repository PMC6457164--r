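# helper: dress a simulated case-control set as analysis records
cc_records <- function(n_cases, n_controls, ..., seed) {
  d <- simulate_case_control(n_cases, n_controls, ..., seed = seed)
  d$dx_depression <- d$status
  d$total_score <- d$score
  d$design_weight <- 1
  d$stratum <- "all"
  d
}

test_that("placement values are correct on a hand-computed fixture", {
  # controls 1,2,2,4 with weights 1,1,1,2: total weight 5
  pv <- placement_values(c(0, 2, 3, 5), c(1, 2, 2, 4), c(1, 1, 1, 2))
  # s=0: all 5 above -> 1; s=2: w>= is 2+2=4, ties 2 -> (4-1)/5
  expect_equal(pv, c(5 / 5, (4 - 1) / 5, 2 / 5, 0))
})

test_that("placement values of controls against themselves have mean 1/2", {
  set.seed(10)
  s <- sample(0:30, 2000, replace = TRUE, prob = dbinom(0:30, 30, 0.25))
  pv <- placement_values(s, s)
  expect_lt(abs(mean(pv) - 0.5), 3 * sd(pv) / sqrt(length(pv)))
  expect_true(all(pv >= 0 & pv <= 1))
})

test_that("placement values decrease in the case score", {
  set.seed(11)
  ctrl <- rnorm(200)
  s <- sort(rnorm(50))
  expect_true(all(diff(placement_values(s, ctrl)) <= 0))
})

test_that("cluster sandwich covariance matches the sandwich package", {
  d <- cc_records(60, 80, mu1 = 1.5, sigma1 = 1.1, beta_age = -0.02, seed = 9)
  tg <- seq(0.05, 0.95, by = 0.05)
  f <- fit_roc_glm(d, covariates = "age", t_grid = tg)
  pv <- placement_values(d$score[d$status == 1], d$score[d$status == 0])
  nc <- sum(d$status == 1)
  long <- data.frame(
    U = as.vector(vapply(seq_len(nc), function(i) as.numeric(pv[i] <= tg),
                         numeric(length(tg)))),
    qt = rep(qnorm(tg), nc),
    age = rep(d$age[d$status == 1], each = length(tg)),
    id = rep(seq_len(nc), each = length(tg)))
  g <- suppressWarnings(glm(U ~ qt + age, data = long,
                            family = quasibinomial("probit")))
  expect_equal(unname(f$coefficients), unname(coef(g)), tolerance = 1e-10)
  V <- sandwich::vcovCL(g, cluster = long$id)
  expect_equal(unname(f$vcov), unname(V), tolerance = 1e-3)
})

test_that("binormal parameters are recovered from model-generated data", {
  # truth alpha0 = 1.2, alpha1 = 0.9, beta = -0.3 on a decade-scaled age;
  # latent-scale equivalents mu1 = a0/a1, sigma1 = 1/a1, slope = beta*sigma1
  sigma1 <- 1 / 0.9
  d <- cc_records(1000, 1000, mu1 = 1.2 / 0.9, sigma1 = sigma1,
                  beta_age = -0.3 * sigma1 / 10, seed = 71, discretise = FALSE)
  d$age_dec <- (d$age - 30) / 10
  f <- fit_roc_glm(d, covariates = "age_dec")
  se <- sqrt(diag(f$vcov))
  expect_lt(abs(f$alpha0 - 1.2), 3 * se[1])
  expect_lt(abs(f$alpha1 - 0.9), 3 * se[2])
  expect_lt(abs(f$beta[["age_dec"]] - (-0.3)), 3 * se[3])
})

test_that("reference AUC identity and empirical agreement hold", {
  d <- cc_records(1500, 1500, mu1 = 1.78, sigma1 = 1, seed = 81)
  f <- fit_roc_glm(d)
  expect_equal(roc_glm_auc(f),
               pnorm(f$alpha0 / sqrt(1 + f$alpha1^2)), tolerance = 1e-12)
  emp <- empirical_roc(d)
  expect_lt(abs(roc_glm_auc(f) - emp$auc), 0.02)
  # fitted curve close to the empirical one at interior points
  pts <- emp$points
  for (t in c(0.1, 0.25, 0.5)) {
    emp_t <- approx(pts$fpr, pts$tpr, xout = t, ties = max)$y
    fit_t <- roc_glm_curve(f, t)$roc
    expect_lt(abs(fit_t - emp_t), 0.02)
  }
})

test_that("single-covariate Wald test equals the squared z statistic", {
  d <- cc_records(120, 150, mu1 = 1.6, sigma1 = 1, beta_age = -0.03, seed = 5)
  f <- fit_roc_glm(d, covariates = "age")
  b <- f$beta[["age"]]
  se_b <- sqrt(f$vcov["age", "age"])
  g <- compare_roc_groups(f, "age")
  expect_equal(g$chi2, (b / se_b)^2, tolerance = 1e-10)
  expect_equal(g$df, 1)
  expect_equal(g$p, pchisq((b / se_b)^2, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_error(compare_roc_groups(f, "income"), "not in fit")
})

test_that("categorical covariates get a joint multi-df Wald test", {
  d <- cc_records(200, 200, mu1 = 1.7, sigma1 = 1, seed = 15)
  d$ethnicity <- sample(paste0("eth", 1:4), nrow(d), replace = TRUE)
  f <- fit_roc_glm(d, covariates = "ethnicity")
  g <- compare_roc_groups(f, "ethnicity")
  expect_equal(g$df, 3)
  expect_gte(g$p, 0)
  # zero beta block implies a zero statistic
  f0 <- f
  f0$coefficients[3:5] <- 0
  f0$wald$chi2 <- 0; f0$wald$p <- 1
  expect_equal(compare_roc_groups(f0, "ethnicity")$chi2, 0)
})

test_that("an age effect of realistic size is detected with high power", {
  # latent slope -0.04/yr over ages 16-45 at 500 cases: the Wald test should
  # reject far more often than not
  rej <- vapply(1:30, function(r) {
    d <- cc_records(500, 500, mu1 = 1.78, sigma1 = 1, beta_age = -0.04,
                    seed = 600 + r)
    compare_roc_groups(fit_roc_glm(d, covariates = "age"), "age")$p < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.8)
})

test_that("insufficient groups and bad grids raise errors", {
  d <- cc_records(10, 10, seed = 2)
  expect_error(fit_roc_glm(d), "at least 20")
  d <- cc_records(30, 30, seed = 3)
  expect_error(fit_roc_glm(d, t_grid = c(0, 0.5)), "strictly in")
  d$dup <- d$age
  expect_error(fit_roc_glm(d, covariates = c("age", "dup")), "collinear")
})
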