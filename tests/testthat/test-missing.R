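random_items <- function(n, seed, miss_cells = 0) {
  set.seed(seed)
  m <- matrix(sample(0:3, n * 10, replace = TRUE), n, 10,
              dimnames = list(NULL, paste0("item_", 1:10)))
  if (miss_cells > 0) {
    # at most 3 missing per row so nobody is excluded
    rows <- sample(n, miss_cells, replace = TRUE)
    for (r in unique(rows)) {
      k <- min(3, sum(rows == r))
      m[r, sample(10, k)] <- NA
    }
  }
  as.data.frame(m)
}

test_that("complete data pass through imputation unchanged", {
  items <- random_items(40, seed = 1)
  res <- pmm_impute(items, seed = 2)
  expect_identical(res$items, items)
  expect_false(any(res$imputed_mask))
  expect_length(res$excluded_ids, 0)
})

test_that("records with more than 30% items missing are excluded, untouched", {
  items <- random_items(20, seed = 3)
  items[5, 1:4] <- NA   # 4 of 10 missing
  items[9, 1:2] <- NA   # 2 of 10 -> imputed
  res <- pmm_impute(items, seed = 4, ids = paste0("w", 1:20))
  expect_identical(res$excluded_ids, "w5")
  expect_true(all(is.na(res$items[5, 1:4])))
  expect_false(anyNA(res$items[9, ]))
})

test_that("imputed values come from observed donors and observed cells persist", {
  for (seed in 1:100) {
    items <- random_items(30, seed = seed, miss_cells = 8)
    res <- pmm_impute(items, seed = seed + 1000)
    obs_mask <- !is.na(items)
    # observed cells bitwise unchanged
    expect_identical(as.matrix(res$items)[obs_mask],
                     as.matrix(items)[obs_mask])
    # each imputed value occurs among the observed values of its item
    for (j in seq_len(ncol(items))) {
      filled <- res$imputed_mask[, j]
      if (any(filled))
        expect_true(all(res$items[filled, j] %in%
                          items[!is.na(items[, j]), j]))
    }
  }
})

test_that("imputation is deterministic given the seed and logs donors", {
  items <- random_items(50, seed = 7, miss_cells = 10)
  a <- pmm_impute(items, seed = 99)
  b <- pmm_impute(items, seed = 99)
  expect_identical(a$items, b$items)
  expect_equal(nrow(a$donors), sum(a$imputed_mask))
})

test_that("response model recovers known missingness coefficients", {
  cfg <- cohort_config(n_screen = 5000, item_missing = 0, consent_rate = 1,
                       module_missing_coef = c(intercept = 2, total_score = -0.12,
                                               employment = 0.5, eth2 = 0,
                                               eth3 = 0, eth4 = 0, eth5 = 0))
  pop <- generate_population(cfg, seed = 12)
  pop <- with_total_score(pop)
  m <- fit_response_model(pop, "depression",
                          predictors = c("total_score", "employment"))
  truth <- c(2, -0.12, 0.5)
  est <- m$coefficients
  expect_lt(abs(est[["(Intercept)"]] - truth[1]), 3 * m$se[["(Intercept)"]])
  expect_lt(abs(est[["total_score"]] - truth[2]), 3 * m$se[["total_score"]])
  expect_lt(abs(est[["employment"]] - truth[3]), 3 * m$se[["employment"]])
})

test_that("no missingness gives response probabilities near one", {
  s <- sampled_cohort(config_no_missing(n_screen = 1500), seed = 31)
  int <- with_total_score(s$interviewed)
  m <- fit_response_model(int, "depression")
  expect_true(all(m$fitted > 0.99, na.rm = TRUE))
  int2 <- apply_combined_weights(int, m)
  expect_equal(int2$analysis_weight, int2$design_weight, tolerance = 0.02)
})

test_that("combined weights divide design weights by response probability", {
  rec <- random_weighted_records(40, seed = 17)
  rm_fake <- structure(list(fitted = rep(0.5, 40), module = "depression"),
                       class = "response_model")
  out <- apply_combined_weights(rec, rm_fake)
  expect_equal(out$analysis_weight, rec$design_weight * 2, tolerance = 1e-12)
  rm_one <- structure(list(fitted = rep(1, 40), module = "depression"),
                      class = "response_model")
  out <- apply_combined_weights(rec, rm_one)
  expect_equal(out$analysis_weight, rec$design_weight, tolerance = 1e-12)
})

test_that("probabilities below the floor are capped with a warning", {
  rec <- random_weighted_records(10, seed = 23)
  rm_low <- structure(list(fitted = c(0.001, rep(0.9, 9)),
                           module = "depression"), class = "response_model")
  expect_warning(out <- apply_combined_weights(rec, rm_low), "capped")
  expect_equal(out$analysis_weight[1], rec$design_weight[1] / 0.02)
  expect_true(out$ipw_capped[1])
})

test_that("IPW reproduces frame-scaled totals of module-observed records", {
  # Horvitz-Thompson: sum of analysis weights over module-observed records
  # estimates the frame size
  cfg <- cohort_config(n_screen = 4000, item_missing = 0,
                       module_missing_coef = c(intercept = 2, total_score = -0.1,
                                               employment = 0.3, eth2 = 0,
                                               eth3 = 0, eth4 = 0, eth5 = 0))
  totals <- vapply(1:60, function(r) {
    pop <- generate_population(cfg, seed = 400 + r)
    s <- draw_sample(pop, data.frame(start = 1, k = 4), seed = 800 + r)
    int <- apply_design_weights(s[s$interviewed, ], compute_weights(s))
    int <- with_total_score(int)
    m <- fit_response_model(int, "depression")
    int <- apply_combined_weights(int, m)
    sum(int$analysis_weight, na.rm = TRUE)
  }, numeric(1))
  expect_lt(abs(mean(totals) - cfg$n_screen), 3 * sd(totals) / sqrt(60))
})
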