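# Weighted empirical ROC analysis for an ordinal score. Thresholds sweep the
# observed score values with the rule score >= c; ties between cases and
# controls are handled by the trapezoid, which makes the area identical to the
# weighted mid-rank concordance probability.

roc_inputs <- function(records, score_col, diagnosis_label, weights,
                       weight_col) {
  if (!is.null(weights)) {
    records <- apply_design_weights(records, weights)
    weight_col <- "design_weight"
  }
  dx <- records[[dx_column(diagnosis_label)]]
  mod <- records[[module_column(diagnosis_label)]]
  s <- records[[score_col]]
  w <- records[[weight_col]] %||% rep(1, nrow(records))
  keep <- !is.na(dx) & !is.na(s) & !is.na(w) & (if (is.null(mod)) TRUE else mod)
  list(score = s[keep], case = dx[keep] == 1, w = w[keep])
}

#' Weighted empirical ROC curve
#'
#' Sweeps thresholds over the observed score values (positivity rule
#' `score >= c`), computing design-weighted true- and false-positive rates,
#' and the area under the curve by the trapezoid rule.
#'
#' @param records record data frame.
#' @param score_col column holding the score (default `total_score`).
#' @param diagnosis_label reference diagnosis.
#' @param weights optional `design_weights` to attach.
#' @param weight_col per-record weight column; missing column means weights 1.
#' @return a `roc_curve`: data frame `points` of (threshold, fpr, tpr) from
#'   (1,1) down to (0,0), and `auc`.
#' @export
empirical_roc <- function(records, score_col = "total_score",
                          diagnosis_label = "depression", weights = NULL,
                          weight_col = "design_weight") {
  z <- roc_inputs(records, score_col, diagnosis_label, weights, weight_col)
  if (!any(z$case)) stop("no cases with observed scores")
  if (all(z$case)) stop("no controls with observed scores")
  thr <- sort(unique(z$score))
  w_case <- sum(z$w[z$case]); w_ctrl <- sum(z$w[!z$case])
  tpr <- vapply(thr, function(c) sum(z$w[z$case & z$score >= c]), numeric(1)) / w_case
  fpr <- vapply(thr, function(c) sum(z$w[!z$case & z$score >= c]), numeric(1)) / w_ctrl
  pts <- data.frame(threshold = c(-Inf, thr, Inf),
                    fpr = c(1, fpr, 0), tpr = c(1, tpr, 0))
  o <- order(pts$fpr, pts$tpr)   # ascending from (0,0) to (1,1)
  pts <- pts[o, ]
  auc <- sum(diff(pts$fpr) * (pts$tpr[-1] + pts$tpr[-nrow(pts)]) / 2)
  structure(list(points = pts, auc = auc,
                 weighted = !all(z$w == z$w[1]),
                 n_cases = sum(z$case), n_controls = sum(!z$case)),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("<roc_curve> AUC =", round_half_up(x$auc, 3),
      sprintf("(%d cases, %d controls%s)\n", x$n_cases, x$n_controls,
              if (x$weighted) ", weighted" else ""))
  invisible(x)
}

#' Weighted concordance probability by exhaustive pairs
#'
#' Brute-force AUC: over all case-control pairs,
#' `sum(w_i w_j (1[s_i > s_j] + 0.5 * 1[s_i = s_j])) / (W_case W_ctrl)`.
#' Quadratic in n; intended as an independent check of [empirical_roc()].
#'
#' @inheritParams empirical_roc
#' @return the concordance probability.
#' @export
concordance_auc <- function(records, score_col = "total_score",
                            diagnosis_label = "depression", weights = NULL,
                            weight_col = "design_weight") {
  z <- roc_inputs(records, score_col, diagnosis_label, weights, weight_col)
  sc <- z$score[z$case]; wc <- z$w[z$case]
  s0 <- z$score[!z$case]; w0 <- z$w[!z$case]
  num <- 0
  for (i in seq_along(sc))
    num <- num + wc[i] * sum(w0 * ((sc[i] > s0) + 0.5 * (sc[i] == s0)))
  num / (sum(wc) * sum(w0))
}

#' Accuracy at a list of cut-offs
#'
#' One row of weighted accuracy estimates per cut-off (positivity rule
#' `score >= cutoff`), with Youden's J (Se + Sp - 1) and a flag on the row
#' maximising it. The full table is always returned so any other optimality
#' criterion can be applied.
#'
#' @inheritParams empirical_roc
#' @param cutoffs integer cut-offs to tabulate.
#' @return data frame: cutoff, sensitivity, specificity, ppv, npv, lr_pos,
#'   lr_neg, youden, optimal.
#' @export
cutpoint_table <- function(records, score_col = "total_score",
                           diagnosis_label = "depression", weights = NULL,
                           weight_col = "design_weight", cutoffs = 1:30) {
  if (length(cutoffs) == 0) stop("cutoffs must be non-empty")
  if (any(cutoffs != round(cutoffs))) stop("cutoffs must be integers")
  if (!is.null(weights)) {
    records <- apply_design_weights(records, weights)
    weight_col <- "design_weight"
  }
  if (score_col != "total_score") records$total_score <- records[[score_col]]
  rows <- lapply(cutoffs, function(cc) {
    a <- accuracy_from_2x2(weighted_2x2(records, test_definition("score_threshold", cc),
                                        diagnosis_label, weight_col = weight_col))
    data.frame(cutoff = cc, sensitivity = a$sensitivity,
               specificity = a$specificity, ppv = a$ppv, npv = a$npv,
               lr_pos = a$lr_pos, lr_neg = a$lr_neg,
               youden = a$sensitivity + a$specificity - 1)
  })
  out <- do.call(rbind, rows)
  out$optimal <- seq_len(nrow(out)) == which.max(out$youden)
  out
}
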