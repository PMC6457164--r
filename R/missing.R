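# Missing data handling: single-round predictive mean matching for
# questionnaire items (records with more than 30% of items missing are never
# imputed and are listed for exclusion), and inverse-probability weights for
# gold-standard modules missing at random given the questionnaire total,
# ethnicity and employment.

#' Predictive mean matching for questionnaire items
#'
#' Single round, no chained iterations. For each item with missing cells, a
#' linear regression of the item on the mean of the record's other observed
#' items plus any extra predictors is fitted on complete donors; each missing
#' cell is filled with the observed value of one of the `donor_k` donors
#' closest in predicted mean, drawn uniformly (ties broken by record order).
#' Records missing more than 30% of items are routed to `excluded_ids` and
#' left untouched.
#'
#' @param items data frame or matrix of item scores in `{0,1,2,3}` with `NA`
#'   for missing; rows are records.
#' @param predictors optional data frame of extra fully-observed predictors
#'   (e.g. age), same row order.
#' @param donor_k donor pool size.
#' @param seed integer seed.
#' @param ids record identifiers (default row numbers).
#' @return an `imputation_result`: `items` (completed), `imputed_mask`,
#'   `donors` (data frame row/item/donor id), `excluded_ids`.
#' @export
pmm_impute <- function(items, predictors = NULL, donor_k = 5, seed, ids = NULL) {
  items <- as.data.frame(items)
  k_items <- ncol(items)
  n <- nrow(items)
  ids <- ids %||% as.character(seq_len(n))
  im <- as.matrix(items)
  if (any(!is.na(im) & (im < 0 | im > 3 | im != round(im))))
    stop("item values must be integers in 0-3 or NA")
  set.seed(as.integer(seed))

  n_miss <- rowSums(is.na(im))
  excluded <- n_miss / k_items > 0.3
  mask <- is.na(im) & !excluded

  if (!is.null(predictors)) {
    predictors <- as.data.frame(predictors)
    if (anyNA(predictors)) stop("extra predictors must be fully observed")
  }
  donors_log <- list()
  for (j in seq_len(k_items)) {
    need <- which(mask[, j])
    if (length(need) == 0) next
    other_mean <- rowMeans(im[, -j, drop = FALSE], na.rm = TRUE)
    donor <- which(!excluded & !is.na(im[, j]) & !is.nan(other_mean))
    if (length(donor) == 0)
      stop("no complete donors for item ", colnames(items)[j] %||% j)
    df <- data.frame(y = im[, j], other_mean = other_mean)
    if (!is.null(predictors)) df <- cbind(df, predictors)
    fit <- stats::lm(y ~ ., data = df[donor, , drop = FALSE])
    pred_all <- stats::predict(fit, newdata = df)
    for (i in need) {
      d <- abs(pred_all[donor] - pred_all[i])
      pool <- donor[order(d, donor)[seq_len(min(donor_k, length(donor)))]]
      pick <- pool[sample.int(length(pool), 1)]
      im[i, j] <- im[pick, j]
      donors_log[[length(donors_log) + 1]] <-
        data.frame(row = i, item = j, donor_id = ids[pick])
    }
  }
  out <- as.data.frame(im)
  names(out) <- names(items)
  structure(list(items = out, imputed_mask = mask,
                 donors = if (length(donors_log)) do.call(rbind, donors_log)
                          else data.frame(row = integer(), item = integer(),
                                          donor_id = character()),
                 excluded_ids = ids[excluded]),
            class = "imputation_result")
}

#' Impute questionnaire items within a cohort
#'
#' Applies [pmm_impute()] to the item columns, recomputes `total_score`, and
#' flags excluded records (`epds_excluded`).
#'
#' @param records cohort data frame.
#' @param item_count number of item columns.
#' @param predictors character vector of extra predictor columns (default
#'   `"age"`).
#' @inheritParams pmm_impute
#' @return `records` with completed items, recomputed `total_score`
#'   (`NA` for excluded records), and `epds_excluded` flag; the
#'   `imputation_result` is attached as attribute `imputation`.
#' @export
impute_items <- function(records, item_count = 10L, predictors = "age",
                         donor_k = 5, seed) {
  cols <- paste0("item_", seq_len(item_count))
  res <- pmm_impute(records[cols],
                    predictors = if (length(predictors))
                      records[predictors] else NULL,
                    donor_k = donor_k, seed = seed, ids = records$id)
  records[cols] <- res$items
  records <- with_total_score(records, item_count)
  records$epds_excluded <- records$id %in% res$excluded_ids
  records$total_score[records$epds_excluded] <- NA_real_
  attr(records, "imputation") <- res
  records
}

#' Logistic model for gold-standard module response
#'
#' Fits `module observed ~ total_score + ethnicity + employment` by logistic
#' regression on the interviewed records, mirroring the predictors of module
#' missingness, and attaches fitted response probabilities.
#'
#' @param records interviewed records with `total_score` present.
#' @param module_label diagnosis label whose `module_observed_*` flag is
#'   modelled.
#' @param predictors model predictors (column names).
#' @return a `response_model`: `model` (glm), `coefficients`, `se`,
#'   `fitted` (response probability per record of `records`, `NA` where
#'   predictors are missing).
#' @export
fit_response_model <- function(records, module_label = "depression",
                               predictors = c("total_score", "ethnicity",
                                              "employment")) {
  obs <- records[[module_column(module_label)]]
  if (is.null(obs)) stop("unknown module label: ", module_label)
  df <- records[predictors]
  df$.observed <- as.integer(obs)
  cc <- stats::complete.cases(df)
  if (!any(obs[cc]))
    stop("no observed module responses to model")
  if (all(obs[cc])) {
    # nothing missing: response probability is identically 1
    return(structure(list(model = NULL, coefficients = NULL, se = NULL,
                          fitted = ifelse(cc, 1, NA_real_),
                          degenerate = TRUE, module = module_label,
                          predictors = predictors),
                     class = "response_model"))
  }
  fit <- stats::glm(.observed ~ ., data = df[cc, , drop = FALSE],
                    family = stats::binomial())
  if (!fit$converged || any(abs(stats::coef(fit)) > 15, na.rm = TRUE))
    stop("separation detected in the response model; consider collapsing ",
         "sparse covariate categories")
  p <- rep(NA_real_, nrow(records))
  p[cc] <- stats::predict(fit, newdata = df[cc, , drop = FALSE],
                          type = "response")
  structure(list(model = fit,
                 coefficients = stats::coef(fit),
                 se = sqrt(diag(stats::vcov(fit))),
                 fitted = p, degenerate = FALSE, module = module_label,
                 predictors = predictors),
            class = "response_model")
}

#' @export
print.response_model <- function(x, ...) {
  cat("<response_model> module:", x$module, "\n")
  if (isTRUE(x$degenerate))
    cat("  no missing module responses; probabilities identically 1\n")
  else print(round(cbind(estimate = x$coefficients, se = x$se), 4))
  invisible(x)
}

#' Fit the response model with predictor fallback
#'
#' Tries the full predictor set; when quasi-separation is detected (typical in
#' small samples where a sparse covariate category has no missing modules),
#' refits with progressively simpler predictor sets, recording which set was
#' used. Used by [run_pipeline()].
#'
#' @inheritParams fit_response_model
#' @param predictor_sets list of predictor vectors, tried in order.
#' @return a `response_model` with element `predictors` naming the set used.
#' @export
fit_response_model_safe <- function(records, module_label = "depression",
                                    predictor_sets = list(
                                      c("total_score", "ethnicity", "employment"),
                                      c("total_score", "employment"),
                                      "total_score")) {
  last <- NULL
  for (p in predictor_sets) {
    m <- tryCatch(fit_response_model(records, module_label, predictors = p),
                  error = function(e) e)
    if (!inherits(m, "error")) {
      if (!identical(p, predictor_sets[[1]]))
        message("[twophasedx] response model for '", module_label,
                "' used reduced predictors: ", paste(p, collapse = ", "))
      return(m)
    }
    last <- m
  }
  stop(last)
}

#' Combine design and inverse-probability weights
#'
#' `analysis_weight = design_weight / response_probability` for records with
#' the module observed; records with the module missing get `NA` and are
#' excluded from that module's analyses. Probabilities below `floor` are
#' capped there (weight bounded) and flagged.
#'
#' @param records records with `design_weight`.
#' @param response_model a [fit_response_model()] result.
#' @param floor probability floor (default 0.02).
#' @return `records` with `analysis_weight` and `ipw_capped` columns; a
#'   warning reports the number of capped records.
#' @export
apply_combined_weights <- function(records, response_model, floor = 0.02) {
  if (is.null(records$design_weight)) stop("records lack design_weight")
  p <- response_model$fitted
  stopifnot(length(p) == nrow(records))
  capped <- !is.na(p) & p < floor
  if (any(capped))
    warning(sum(capped), " record(s) had response probability below ", floor,
            "; weight capped")
  p_eff <- pmax(p, floor)
  obs <- records[[module_column(response_model$module)]]
  w <- records$design_weight / p_eff
  w[!obs] <- NA_real_
  records$analysis_weight <- w
  records$ipw_capped <- capped
  records
}
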