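#!/usr/bin/env Rscript
# ROC analysis of the questionnaire score for depression on the synthetic
# sampled cohort: weighted empirical ROC and AUC, the cut-point performance
# table with Youden-optimal row, and the covariate-adjusted ROC regression
# with Wald tests of each covariate's effect on discrimination.

suppressPackageStartupMessages(library(twophasedx))
SEED <- 20260104

pop <- load_cohort_csv("results/cohort_sampled.csv")
int <- pop[pop$interviewed, ]
int <- impute_items(int, seed = SEED)
m <- fit_response_model_safe(int, "depression")
int <- apply_combined_weights(int, m)

roc <- empirical_roc(int, diagnosis_label = "depression",
                     weight_col = "analysis_weight")
print(roc)

cuts <- cutpoint_table(int, diagnosis_label = "depression",
                       weight_col = "analysis_weight", cutoffs = 5:20)
cat("\ncut-point table (Youden-optimal row flagged):\n")
print(within(cuts, {
  sensitivity <- round_half_up(sensitivity, 2)
  specificity <- round_half_up(specificity, 2)
  ppv <- round_half_up(ppv, 2); npv <- round_half_up(npv, 2)
  lr_pos <- round_half_up(lr_pos, 1); lr_neg <- round_half_up(lr_neg, 2)
  youden <- round_half_up(youden, 3)
}), row.names = FALSE)

fit <- fit_roc_glm(int, diagnosis_label = "depression",
                   covariates = c("age", "ethnicity", "income", "education",
                                  "interpreter", "mode"),
                   weight_col = "analysis_weight")
cat("\ncovariate-adjusted ROC regression:\n")
print(fit)

write.csv(roc$points, "results/roc_curve.csv", row.names = FALSE)
write.csv(cuts, "results/cutpoints.csv", row.names = FALSE)
write.csv(fit$wald, "results/roc_wald_tests.csv", row.names = FALSE)
cat("wrote results/roc_curve.csv, results/cutpoints.csv, results/roc_wald_tests.csv\n")
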