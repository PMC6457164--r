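# Covariate-adjusted ROC regression (ROC-GLM) by the placement-value method:
# each case score is ranked against the weighted control score distribution
# (mid-rank for ties), the binary indicators U_it = 1[pv_i <= t] over a grid
# of false-positive rates t are regressed on probit(t) and case covariates
# with a probit link, and inference uses a sandwich covariance clustered on
# the case (each case contributes one row per grid point). Covariates shift
# the ROC curve only; the control distribution is left unadjusted.

#' Weighted placement values of case scores among controls
#'
#' For a case score s, the weighted proportion of controls with score >= s,
#' counting controls tied with s at half weight. Placement values of the
#' controls against their own distribution are uniform in expectation.
#'
#' @param case_scores numeric scores of cases.
#' @param control_scores numeric scores of controls.
#' @param control_weights weights for controls (default 1).
#' @return numeric vector in `[0, 1]`, one per case.
#' @export
placement_values <- function(case_scores, control_scores,
                             control_weights = rep(1, length(control_scores))) {
  stopifnot(length(control_scores) == length(control_weights))
  o <- order(control_scores)
  s0 <- control_scores[o]; w0 <- control_weights[o]
  tot <- sum(w0)
  cw <- c(0, cumsum(w0))                 # cw[k+1] = weight of first k controls
  # findInterval(s, s0, left.open = TRUE) counts controls strictly below s;
  # without left.open it counts controls at or below s
  w_lt <- cw[findInterval(case_scores, s0, left.open = TRUE) + 1]
  w_le <- cw[findInterval(case_scores, s0) + 1]
  w_eq <- w_le - w_lt
  w_ge <- tot - w_le + w_eq
  (w_ge - 0.5 * w_eq) / tot
}

# IRLS probit fit (quasi-binomial) returning coefficients, the expected
# information A = X'WX, and per-row score contributions for the sandwich.
probit_fit <- function(X, y, w) {
  fit <- suppressWarnings(
    stats::glm.fit(X, y, weights = w,
                   family = stats::quasibinomial(link = "probit")))
  beta <- fit$coefficients
  if (anyNA(beta)) {
    bad <- names(beta)[is.na(beta)]
    stop("singular design in ROC regression; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  eta <- drop(X %*% beta)
  mu <- stats::pnorm(eta)
  mu <- pmin(pmax(mu, 1e-10), 1 - 1e-10)
  phi <- stats::dnorm(eta)
  v <- mu * (1 - mu)
  A <- crossprod(X * sqrt(w * phi^2 / v))
  score <- X * (w * (y - mu) * phi / v)
  list(coef = beta, A = A, score = score, converged = fit$converged)
}

#' Fit a covariate-adjusted ROC regression
#'
#' Model: `ROC_Z(t) = pnorm(alpha0 + alpha1 * qnorm(t) + beta %*% Z)`.
#' Estimation follows the parametric distribution-free placement-value
#' approach: weighted case placement values against the (unadjusted, weighted)
#' control score distribution; probit regression of the indicators
#' `1[pv <= t]` over `t_grid` on `qnorm(t)` and the case covariates, weighted
#' by the case analysis weights; Wald chi-square tests per covariate from a
#' case-clustered sandwich covariance.
#'
#' @param records record data frame.
#' @param score_col score column.
#' @param diagnosis_label reference diagnosis; cases are records with the flag
#'   set, controls those without.
#' @param covariates character vector of covariate column names (numeric or
#'   categorical) entering the ROC model for cases.
#' @param weights optional `design_weights` to attach.
#' @param weight_col per-record weight column (missing column = weights 1).
#' @param t_grid grid of false-positive rates in (0, 1).
#' @param min_group minimum number of cases and controls required.
#' @return a `roc_glm_fit`: `alpha0`, `alpha1`, `beta`, `coefficients`,
#'   `vcov` (cluster sandwich), `wald` (per covariate group), counts, and
#'   `alpha1_nonpositive` warning flag.
#' @export
fit_roc_glm <- function(records, score_col = "total_score",
                        diagnosis_label = "depression",
                        covariates = character(), weights = NULL,
                        weight_col = "design_weight",
                        t_grid = seq(0.01, 0.99, by = 0.01),
                        min_group = 20) {
  if (any(t_grid <= 0 | t_grid >= 1)) stop("t_grid must lie strictly in (0, 1)")
  if (!is.null(weights)) {
    records <- apply_design_weights(records, weights)
    weight_col <- "design_weight"
  }
  dx <- records[[dx_column(diagnosis_label)]]
  mod <- records[[module_column(diagnosis_label)]]
  s <- records[[score_col]]
  w <- records[[weight_col]] %||% rep(1, nrow(records))
  ok <- !is.na(dx) & !is.na(s) & !is.na(w) &
    (if (is.null(mod)) TRUE else mod)
  if (length(covariates) > 0)
    ok <- ok & stats::complete.cases(records[covariates])
  case <- ok & dx == 1
  ctrl <- ok & dx == 0
  if (sum(case) < min_group || sum(ctrl) < min_group)
    stop("need at least ", min_group, " cases and controls (have ",
         sum(case), " / ", sum(ctrl), ")")

  pv <- placement_values(s[case], s[ctrl], w[ctrl])
  nc <- sum(case); nt <- length(t_grid)

  # design: rows are case x t, ordered case-major
  U <- as.numeric(outer(pv, t_grid, `<=`))          # nc x nt, then flattened
  U <- as.vector(t(matrix(U, nc, nt)))              # case-major order
  qt <- rep(stats::qnorm(t_grid), times = nc)
  if (length(covariates) > 0) {
    cov_df <- records[case, covariates, drop = FALSE]
    for (nm in covariates)
      if (is.character(cov_df[[nm]])) cov_df[[nm]] <- factor(cov_df[[nm]])
    mm <- stats::model.matrix(~ ., data = cov_df)
    asg <- attr(mm, "assign")
    Z <- mm[, -1, drop = FALSE]
    group_of <- covariates[asg[-1]]
    Zrep <- Z[rep(seq_len(nc), each = nt), , drop = FALSE]
  } else {
    Zrep <- matrix(numeric(0), nc * nt, 0)
    group_of <- character(0)
  }
  X <- cbind(`(Intercept)` = 1, `qnorm(t)` = qt, Zrep)
  wrow <- rep(w[case], each = nt)
  cluster <- rep(seq_len(nc), each = nt)

  f <- probit_fit(X, U, wrow)
  # cluster-robust sandwich: sum score contributions within case
  S <- rowsum(f$score, cluster)
  meat <- crossprod(S) * nc / (nc - 1)
  Ainv <- solve(f$A)
  V <- Ainv %*% meat %*% Ainv
  dimnames(V) <- list(colnames(X), colnames(X))

  coef <- f$coef
  names(coef) <- colnames(X)
  beta <- coef[-(1:2)]
  wald <- NULL
  if (length(covariates) > 0) {
    wald <- do.call(rbind, lapply(unique(group_of), function(g) {
      ix <- which(c(FALSE, FALSE, group_of == g))
      b <- coef[ix]
      chi2 <- drop(t(b) %*% solve(V[ix, ix, drop = FALSE]) %*% b)
      data.frame(covariate = g, chi2 = chi2, df = length(ix),
                 p = stats::pchisq(chi2, length(ix), lower.tail = FALSE))
    }))
  }
  structure(list(alpha0 = unname(coef[1]), alpha1 = unname(coef[2]),
                 beta = beta, coefficients = coef, vcov = V, wald = wald,
                 group_of = group_of, t_grid = t_grid,
                 n_cases = nc, n_controls = sum(ctrl),
                 converged = f$converged,
                 alpha1_nonpositive = unname(coef[2] <= 0)),
            class = "roc_glm_fit")
}

#' @export
print.roc_glm_fit <- function(x, ...) {
  cat("<roc_glm_fit> ROC_Z(t) = pnorm(alpha0 + alpha1 qnorm(t) + beta Z)\n")
  se <- sqrt(diag(x$vcov))
  print(round(cbind(estimate = x$coefficients, se = se), 4))
  if (!is.null(x$wald)) {
    cat("Wald tests (cluster-robust):\n")
    print(x$wald, row.names = FALSE)
  }
  if (x$alpha1_nonpositive)
    cat("warning: fitted alpha1 <= 0 (non-monotone ROC parameterisation)\n")
  cat("reference-covariate AUC:", round_half_up(roc_glm_auc(x), 3), "\n")
  invisible(x)
}

#' Covariate-specific AUC from a fitted ROC regression
#'
#' `AUC(Z) = pnorm((alpha0 + beta %*% z) / sqrt(1 + alpha1^2))`.
#'
#' @param fit a `roc_glm_fit`.
#' @param z named numeric vector over the model-matrix columns of the
#'   covariates (default all zero = reference).
#' @return the AUC.
#' @export
roc_glm_auc <- function(fit, z = NULL) {
  shift <- if (is.null(z)) 0 else sum(fit$beta[names(z)] * z)
  stats::pnorm((fit$alpha0 + shift) / sqrt(1 + fit$alpha1^2))
}

#' Predicted ROC curve from a fitted ROC regression
#'
#' @param fit a `roc_glm_fit`.
#' @param t false-positive rates.
#' @param z as in [roc_glm_auc()].
#' @return data frame (t, roc).
#' @export
roc_glm_curve <- function(fit, t = fit$t_grid, z = NULL) {
  shift <- if (is.null(z)) 0 else sum(fit$beta[names(z)] * z)
  data.frame(t = t,
             roc = stats::pnorm(fit$alpha0 + shift + fit$alpha1 * stats::qnorm(t)))
}

#' Wald test of a covariate group's effect on the ROC curve
#'
#' @param fit a `roc_glm_fit`.
#' @param covariate_group name of a covariate passed to [fit_roc_glm()].
#' @return list `(chi2, df, p)`.
#' @export
compare_roc_groups <- function(fit, covariate_group) {
  if (is.null(fit$wald) || !covariate_group %in% fit$wald$covariate)
    stop("covariate group '", covariate_group, "' not in fit")
  row <- fit$wald[fit$wald$covariate == covariate_group, ]
  list(chi2 = row$chi2, df = row$df, p = row$p)
}
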