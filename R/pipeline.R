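# End-to-end synthetic study: simulate -> sample -> impute -> IPW ->
# weighted accuracy for the four test definitions -> prevalences ->
# cut-point table -> covariate-adjusted ROC regression, with a JSON report
# and a run manifest for reproducibility.

config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(config, f, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(f))
}

#' Run the full two-phase analysis pipeline on a synthetic cohort
#'
#' Generates a screened population, draws the stratified verification sample,
#' computes design weights, imputes questionnaire items (predictive mean
#' matching), fits the module-response model and combines inverse-probability
#' weights with the design weights, then estimates weighted accuracy for the
#' four test definitions (either question, both questions, either plus help,
#' and the 12/13 score cut-off) against depression and any disorder,
#' prevalences, the cut-point table, and the covariate-adjusted ROC
#' regression.
#'
#' @param config a [cohort_config()].
#' @param seed integer master seed; stage seeds are derived from it.
#' @param out_dir optional directory; when given, the cohort CSV, report JSON,
#'   frame-totals sidecar and manifest JSON are written there.
#' @param schedule negative-sampling schedule for [draw_sample()].
#' @param boot_B bootstrap replicates for confidence intervals.
#' @param roc_covariates covariates for the ROC regression.
#' @param cutoffs cut-offs for the cut-point table.
#' @return list with `report` (all estimates), `records` (interviewed,
#'   weighted), `weights`, and `manifest`.
#' @export
run_pipeline <- function(config = cohort_config(), seed = 1, out_dir = NULL,
                         schedule = data.frame(start = c(1, floor(config$n_screen / 2) + 1),
                                               k = c(4, 6)),
                         boot_B = 1000,
                         roc_covariates = c("age", "ethnicity", "income",
                                            "education", "interpreter", "mode"),
                         cutoffs = 5:20) {
  seeds <- derive_seeds(seed, 6)
  log_line <- function(...) message("[twophasedx] ", ...)

  population <- generate_population(config, seed = seeds[1])
  log_line("simulate: ", nrow(population), " women screened, ",
           sum(population$stratum == "positive"), " screen-positive")

  population <- draw_sample(population, schedule, seed = seeds[2])
  weights <- compute_weights(population)
  sample_df <- population[population$interviewed, , drop = FALSE]
  sample_df <- apply_design_weights(sample_df, weights)
  log_line("sample: ", nrow(sample_df), " interviewed (",
           sum(sample_df$stratum == "positive"), "+ / ",
           sum(sample_df$stratum == "negative"), "-)")

  n_item_missing <- sum(is.na(sample_df[paste0("item_", 1:config$item_count)]))
  sample_df <- impute_items(sample_df, config$item_count, donor_k = 5,
                            seed = seeds[3])
  imp <- attr(sample_df, "imputation")
  log_line("impute: ", n_item_missing, " missing cells, ",
           sum(imp$imputed_mask), " imputed, ",
           length(imp$excluded_ids), " records excluded (>30% missing)")

  resp <- lapply(c(depression = "depression", any = "any"), function(lbl)
    fit_response_model_safe(sample_df, lbl))
  ipw <- lapply(resp, function(m) apply_combined_weights(sample_df, m))

  tests <- list(either = test_definition("either_positive"),
                both = test_definition("both_positive"),
                help = test_definition("either_plus_help"),
                epds_13 = test_definition("score_threshold", 13))
  accuracy <- list()
  for (lbl in c("depression", "any")) {
    rec <- ipw[[if (lbl == "any") "any" else "depression"]]
    accuracy[[lbl]] <- lapply(tests, function(tt)
      estimate_accuracy(rec, tt, lbl, weight_col = "analysis_weight",
                        B = boot_B, seed = seeds[4]))
  }
  log_line("estimate: 4 tests x 2 diagnoses, B = ", boot_B)

  prev <- prevalence_estimates(ipw$depression, c("depression", "any"),
                               weight_col = "analysis_weight",
                               B = boot_B, seed = seeds[4])
  cuts <- cutpoint_table(ipw$depression, diagnosis_label = "depression",
                         weight_col = "analysis_weight", cutoffs = cutoffs)
  roc <- empirical_roc(ipw$depression, diagnosis_label = "depression",
                       weight_col = "analysis_weight")
  roc_fit <- fit_roc_glm(ipw$depression, diagnosis_label = "depression",
                         covariates = roc_covariates,
                         weight_col = "analysis_weight")
  log_line("roc: empirical AUC ", round_half_up(roc$auc, 3),
           ", model AUC ", round_half_up(roc_glm_auc(roc_fit), 3))

  report <- list(
    design_weights = as.data.frame(weights),
    prevalence = prev,
    accuracy = lapply(accuracy, function(per_test) lapply(per_test, function(a)
      list(estimates = a[c("sensitivity", "specificity", "ppv", "npv",
                           "lr_pos", "lr_neg", "prevalence")],
           ci = a$ci,
           raw_cells = a$table[c("raw_tp", "raw_fp", "raw_fn", "raw_tn")],
           weighted_cells = a$table[c("tp", "fp", "fn", "tn")],
           n_excluded = a$table$n_excluded))),
    cutpoints = cuts,
    empirical_auc = roc$auc,
    roc_glm = list(alpha0 = roc_fit$alpha0, alpha1 = roc_fit$alpha1,
                   beta = as.list(roc_fit$beta), wald = roc_fit$wald,
                   auc_reference = roc_glm_auc(roc_fit)),
    response_models = lapply(resp, function(m) as.list(m$coefficients)))

  manifest <- list(config_hash = config_hash(config), seed = seed,
                   stage_seeds = seeds,
                   package_version = as.character(utils::packageVersion("twophasedx")),
                   n_screen = nrow(population), n_interviewed = nrow(sample_df),
                   timestamp = format(Sys.time(), tz = "UTC"),
                   outputs = character(0))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- file.path(out_dir, c("cohort.csv", "frame_totals.json",
                                  "report.json", "manifest.json"))
    write_cohort_csv(apply_design_weights(population, weights), paths[1],
                     config$item_count)
    jsonlite::write_json(as.data.frame(weights), paths[2], digits = NA)
    write_report(report, paths[3])
    manifest$outputs <- paths[1:3]
    jsonlite::write_json(manifest, paths[4], auto_unbox = TRUE, digits = NA)
  }
  list(report = report, records = ipw, weights = weights, manifest = manifest)
}

# independent stage seeds derived from one master seed (kept below 2^31)
derive_seeds <- function(seed, n) {
  set.seed(as.integer(seed))
  sample.int(2^31 - 1, n)
}

#' Write an analysis report as JSON
#'
#' @param report a list (e.g. from [run_pipeline()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, dataframe = "rows", na = "null")
  invisible(path)
}
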