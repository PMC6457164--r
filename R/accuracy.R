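# Weighted 2x2 tables and diagnostic accuracy under the two-phase design.
# Each cell is a sum of design weights; sensitivity, specificity, predictive
# values and likelihood ratios follow from the weighted table, which removes
# the verification bias induced by oversampling screen-positives.

#' Define an index-test positivity rule
#'
#' Four rules are supported: `either_positive` (yes to either screen
#' question), `both_positive` (yes to both), `either_plus_help` (screen
#' positive and yes to the help question), and `score_threshold`
#' (questionnaire total >= `cutoff`; the conventional "12/13" cut-off is
#' `cutoff = 13`).
#'
#' @param rule one of the four rule names.
#' @param cutoff integer threshold in `[1, 30]`, required for
#'   `score_threshold`.
#' @param name optional display name.
#' @return a `test_definition`.
#' @export
test_definition <- function(rule = c("either_positive", "both_positive",
                                     "either_plus_help", "score_threshold"),
                            cutoff = NULL, name = NULL) {
  rule <- match.arg(rule)
  if (rule == "score_threshold") {
    if (is.null(cutoff) || length(cutoff) != 1 || cutoff != round(cutoff) ||
        cutoff < 1 || cutoff > 30)
      stop("score_threshold requires an integer cutoff in [1, 30]")
    cutoff <- as.integer(cutoff)
  } else if (!is.null(cutoff)) {
    stop("cutoff only applies to the score_threshold rule")
  }
  structure(list(rule = rule, cutoff = cutoff,
                 name = name %||% if (rule == "score_threshold")
                   paste0("score>=", cutoff) else rule),
            class = "test_definition")
}

#' Evaluate a test rule on records
#'
#' @param records cohort data frame.
#' @param test a [test_definition()].
#' @return logical vector; `NA` where the rule is unevaluable (help answer or
#'   total score missing).
#' @export
evaluate_test <- function(records, test) {
  switch(test$rule,
    either_positive = records$screen_q1 == 1 | records$screen_q2 == 1,
    both_positive = records$screen_q1 == 1 & records$screen_q2 == 1,
    either_plus_help = {
      pos <- records$screen_q1 == 1 | records$screen_q2 == 1
      ifelse(pos, pos & records$help_q == 1, FALSE)
    },
    score_threshold = records$total_score >= test$cutoff)
}

dx_column <- function(diagnosis_label) {
  lbl <- sub("^dx_", "", diagnosis_label)
  if (lbl == "any_disorder") lbl <- "any"
  paste0("dx_", lbl)
}

module_column <- function(diagnosis_label) {
  lbl <- sub("^dx_", "", diagnosis_label)
  if (lbl == "any_disorder") lbl <- "any"
  paste0("module_observed_", lbl)
}

# rows usable for a given test/diagnosis: observed diagnosis + evaluable rule
usable_rows <- function(records, test, diagnosis_label) {
  dx <- records[[dx_column(diagnosis_label)]]
  if (is.null(dx)) stop("unknown diagnosis label: ", diagnosis_label)
  mod <- records[[module_column(diagnosis_label)]]
  obs <- !is.na(dx) & (if (is.null(mod)) TRUE else mod)
  ev <- !is.na(evaluate_test(records, test))
  obs & ev
}

#' Weighted 2x2 table of an index test against a reference diagnosis
#'
#' Each cell is the sum of analysis weights of the interviewed records falling
#' in it; raw integer counts are kept alongside. Records with an unobserved
#' diagnosis module or an unevaluable test rule are excluded and counted.
#'
#' @param records interviewed records carrying a weight column.
#' @param test a [test_definition()].
#' @param diagnosis_label e.g. `"depression"` or `"any"`.
#' @param weights optional `design_weights`; if supplied, weights are looked up
#'   by stratum, otherwise the `weight_col` column of `records` is used.
#' @param weight_col name of the per-record weight column (default
#'   `design_weight`; use `analysis_weight` after [apply_combined_weights()]).
#' @return a `two_by_two`: weighted `tp`, `fp`, `fn`, `tn`, raw counts, and the
#'   number excluded.
#' @export
weighted_2x2 <- function(records, test, diagnosis_label = "depression",
                         weights = NULL, weight_col = "design_weight") {
  if (!is.null(weights))
    records <- apply_design_weights(records, weights)
  w <- records[[weight_col]]
  if (is.null(w)) stop("records have no '", weight_col, "' column")
  keep <- usable_rows(records, test, diagnosis_label) & !is.na(w)
  n_excluded <- sum(!keep)
  if (!any(keep)) stop("no evaluable records for test '", test$name,
                       "' and diagnosis '", diagnosis_label, "'")
  r <- records[keep, , drop = FALSE]
  w <- w[keep]
  pos <- evaluate_test(r, test)
  dx <- r[[dx_column(diagnosis_label)]] == 1
  cells <- function(sel) c(sum(w[sel]), sum(sel))
  tp <- cells(pos & dx); fp <- cells(pos & !dx)
  fn <- cells(!pos & dx); tn <- cells(!pos & !dx)
  structure(list(tp = tp[1], fp = fp[1], fn = fn[1], tn = tn[1],
                 raw_tp = tp[2], raw_fp = fp[2], raw_fn = fn[2], raw_tn = tn[2],
                 n_excluded = n_excluded, test = test$name,
                 diagnosis = diagnosis_label),
            class = "two_by_two")
}

#' @export
print.two_by_two <- function(x, ...) {
  cat("<two_by_two>", x$test, "vs", x$diagnosis, "\n")
  m <- matrix(round_half_up(c(x$tp, x$fp, x$fn, x$tn), 1), 2, byrow = TRUE,
              dimnames = list(c("test+", "test-"), c("D+", "D-")))
  print(m)
  cat("raw counts:", x$raw_tp, x$raw_fp, x$raw_fn, x$raw_tn,
      "| excluded:", x$n_excluded, "\n")
  invisible(x)
}

#' Accuracy measures from a weighted 2x2 table
#'
#' Point estimates only: Se = tp/(tp+fn), Sp = tn/(fp+tn), PPV = tp/(tp+fp),
#' NPV = tn/(fn+tn), LR+ = Se/(1-Sp), LR- = (1-Se)/Sp, prevalence =
#' (tp+fn)/total. Bayes consistency (PPV from Se, Sp and prevalence) holds
#' exactly on the weighted table.
#'
#' @param table a [weighted_2x2()] result.
#' @return an `accuracy_estimates` list; when Sp = 1 the positive likelihood
#'   ratio is `Inf` with `lr_pos_infinite = TRUE`.
#' @export
accuracy_from_2x2 <- function(table) {
  with(table, {
    if (tp + fn <= 0) stop("empty diseased margin (tp + fn = 0)")
    if (fp + tn <= 0) stop("empty non-diseased margin (fp + tn = 0)")
    se <- tp / (tp + fn); sp <- tn / (fp + tn)
    structure(list(
      sensitivity = se, specificity = sp,
      ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
      npv = if (fn + tn > 0) tn / (fn + tn) else NA_real_,
      empty_test_margin = tp + fp <= 0 || fn + tn <= 0,
      lr_pos = if (sp == 1) Inf else se / (1 - sp),
      lr_neg = (1 - se) / sp,
      lr_pos_infinite = sp == 1,
      prevalence = (tp + fn) / (tp + fp + fn + tn),
      table = table), class = "accuracy_estimates")
  })
}

#' @export
print.accuracy_estimates <- function(x, ...) {
  cat("<accuracy_estimates>", x$table$test, "vs", x$table$diagnosis, "\n")
  fmt <- function(v, d = 2) format(round_half_up(v, d), nsmall = d)
  line <- function(nm, v, d = 2) {
    cat(sprintf("  %-12s %s", nm, fmt(v, d)))
    ci <- x$ci[[nm]]
    if (!is.null(ci)) cat(sprintf("  (95%% CI %s-%s)", fmt(ci[1], d), fmt(ci[2], d)))
    cat("\n")
  }
  line("sensitivity", x$sensitivity); line("specificity", x$specificity)
  line("ppv", x$ppv); line("npv", x$npv)
  line("lr_pos", x$lr_pos, 1); line("lr_neg", x$lr_neg, 2)
  line("prevalence", x$prevalence, 3)
  invisible(x)
}

#' Stratified percentile bootstrap confidence interval
#'
#' Resamples records with replacement within each screening stratum, holding
#' the observed stratum sizes fixed and carrying each record's weight with it,
#' then takes percentile quantiles of the replicate estimates.
#'
#' @param records record data frame.
#' @param estimator function of a record data frame returning a numeric scalar
#'   or named vector.
#' @param B number of bootstrap replicates (>= 200).
#' @param seed integer seed.
#' @param strata stratification vector (default the `stratum` column; a single
#'   stratum gives the ordinary iid bootstrap).
#' @param conf confidence level.
#' @return list with `low`, `high` (named as the estimator output), `method`,
#'   `B`, `seed`, and `n_failed` replicates. Errors if more than 1% of
#'   replicates fail.
#' @export
bootstrap_ci <- function(records, estimator, B = 1000, seed,
                         strata = records$stratum, conf = 0.95) {
  if (B < 200) stop("B must be >= 200")
  set.seed(as.integer(seed))
  n <- nrow(records)
  strata <- strata %||% rep("all", n)
  idx_by <- split(seq_len(n), strata)
  reps <- vector("list", B)
  n_failed <- 0
  for (b in seq_len(B)) {
    take <- unlist(lapply(idx_by, function(ix)
      ix[sample.int(length(ix), length(ix), replace = TRUE)]), use.names = FALSE)
    res <- tryCatch(estimator(records[take, , drop = FALSE]),
                    error = function(e) NULL)
    if (is.null(res)) n_failed <- n_failed + 1 else reps[[b]] <- res
  }
  if (n_failed > 0.01 * B)
    stop("estimator failed on ", n_failed, " of ", B, " bootstrap replicates")
  mat <- do.call(rbind, reps[!vapply(reps, is.null, logical(1))])
  a <- (1 - conf) / 2
  list(low = apply(mat, 2, stats::quantile, probs = a, names = FALSE),
       high = apply(mat, 2, stats::quantile, probs = 1 - a, names = FALSE),
       method = "stratified percentile", B = B, seed = seed,
       n_failed = n_failed)
}

#' Full accuracy estimation with bootstrap confidence intervals
#'
#' Convenience wrapper: weighted 2x2, point estimates, and stratified
#' percentile bootstrap CIs for Se, Sp, PPV, NPV, the likelihood ratios and
#' prevalence.
#'
#' @inheritParams weighted_2x2
#' @param B bootstrap replicates.
#' @param seed integer seed for the bootstrap.
#' @return `accuracy_estimates` with a `ci` element (per-measure `(low, high)`).
#' @export
estimate_accuracy <- function(records, test, diagnosis_label = "depression",
                              weights = NULL, weight_col = "design_weight",
                              B = 1000, seed = 1) {
  if (!is.null(weights)) {
    records <- apply_design_weights(records, weights)
    weight_col <- "design_weight"
  }
  est <- accuracy_from_2x2(weighted_2x2(records, test, diagnosis_label,
                                        weight_col = weight_col))
  measures <- c("sensitivity", "specificity", "ppv", "npv",
                "lr_pos", "lr_neg", "prevalence")
  fn <- function(r) {
    a <- accuracy_from_2x2(weighted_2x2(r, test, diagnosis_label,
                                        weight_col = weight_col))
    unlist(a[measures])
  }
  ci <- bootstrap_ci(records, fn, B = B, seed = seed)
  est$ci <- stats::setNames(
    lapply(seq_along(measures), function(i) c(ci$low[i], ci$high[i])), measures)
  est$ci_meta <- ci[c("method", "B", "seed", "n_failed")]
  est
}

#' Weighted prevalence of diagnoses with bootstrap confidence intervals
#'
#' For each label, the Horvitz-Thompson weighted proportion over records with
#' that module observed: `sum(w * D) / sum(w)`. Invariant to rescaling of the
#' weights.
#'
#' @param records interviewed records with a weight column.
#' @param diagnosis_labels character vector of labels.
#' @param weights optional `design_weights` to attach first.
#' @param weight_col weight column to use.
#' @param B,seed bootstrap control (set `B = 0` to skip CIs).
#' @return data frame: label, prevalence, low, high, n_observed.
#' @export
prevalence_estimates <- function(records, diagnosis_labels = c("depression", "any"),
                                 weights = NULL, weight_col = "design_weight",
                                 B = 1000, seed = 1) {
  if (!is.null(weights)) {
    records <- apply_design_weights(records, weights)
    weight_col <- "design_weight"
  }
  one <- function(r, lbl) {
    dx <- r[[dx_column(lbl)]]
    mod <- r[[module_column(lbl)]]
    w <- r[[weight_col]]
    keep <- !is.na(dx) & !is.na(w) & (if (is.null(mod)) TRUE else mod)
    if (!any(keep)) stop("diagnosis '", lbl, "' never observed")
    sum(w[keep] * dx[keep]) / sum(w[keep])
  }
  rows <- lapply(diagnosis_labels, function(lbl) {
    est <- one(records, lbl)
    lo <- hi <- NA_real_
    if (B > 0) {
      ci <- bootstrap_ci(records, function(r) one(r, lbl), B = B, seed = seed)
      lo <- ci$low; hi <- ci$high
    }
    mod <- records[[module_column(lbl)]]
    keep <- !is.na(records[[dx_column(lbl)]]) & (if (is.null(mod)) TRUE else mod)
    data.frame(label = lbl, prevalence = est, low = lo, high = hi,
               n_observed = sum(keep))
  })
  do.call(rbind, rows)
}

#' Expand grouped counts into per-record rows
#'
#' Builds a minimal record table from printed group counts (e.g. "130 of 287
#' screen-positive women had the diagnosis"), for reconstructing published
#' weighted tables. Each row of `groups` describes one homogeneous group and
#' is repeated `n` times.
#'
#' @param groups data frame with a column `n` plus any record columns
#'   (`stratum`, `screen_q1`, `screen_q2`, `help_q`, `dx_depression`, ...).
#' @return a record data frame with `n` dropped; module-observed flags default
#'   to `TRUE` for the diagnosis columns present.
#' @export
records_from_counts <- function(groups) {
  stopifnot("n" %in% names(groups))
  out <- groups[rep(seq_len(nrow(groups)), groups$n),
                setdiff(names(groups), "n"), drop = FALSE]
  rownames(out) <- NULL
  for (lbl in c("depression", "any")) {
    mc <- paste0("module_observed_", lbl)
    if (!is.null(out[[paste0("dx_", if (lbl == "any") "any" else lbl)]]) &&
        is.null(out[[mc]]))
      out[[mc]] <- TRUE
  }
  out
}
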