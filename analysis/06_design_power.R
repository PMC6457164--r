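#!/usr/bin/env Rscript
# Design calculations for the planned two-phase study: closed-form expected
# yields, simulated bootstrap CI widths of the weighted Se/Sp estimators, and
# the cases-only power of the sensitivity comparison (0.80 vs 0.65).

suppressPackageStartupMessages(library(twophasedx))
SEED <- 20260106

design <- design_config(n_interview_pos = 400, n_interview_neg = 200,
                        seed = SEED)
y <- expected_yield(design)
cat(sprintf("planned interviews: %d screen-positive + %d screen-negative\n",
            y$rounded[["n_pos"]], y$rounded[["n_neg"]]))
cat(sprintf("expected depressed interviewees: %.2f -> %d\n",
            y$expected_cases, y$rounded[["cases"]]))
yf <- expected_yield(design_config())
cat(sprintf("(fraction-derived equivalent: %.1f+ / %.1f- -> %.1f cases)\n",
            yf$expected_n_pos, yf$expected_n_neg, yf$expected_cases))

w <- simulate_ci_width(design_config(replicates = 100, bootstrap_B = 500,
                                     seed = SEED))
cat(sprintf("bootstrap 95%% CI widths: Se %.3f (MC SE %.4f), Sp %.3f (MC SE %.4f)\n",
            w$ci_width_sens, w$mc_se_sens, w$ci_width_spec, w$mc_se_spec))

p <- simulate_power(design, n_cases = 185, replicates = 5000, seed = SEED)
print(p)

jsonlite::write_json(list(
  expected_yield = y[c("expected_n_pos", "expected_n_neg", "expected_cases")],
  expected_cases_rounded = unname(y$rounded[["cases"]]),
  ci_width = w[c("ci_width_sens", "mc_se_sens", "ci_width_spec", "mc_se_spec")],
  power = p$power, power_mc_se = p$mc_se),
  "results/design_power.json", auto_unbox = TRUE, digits = NA)
cat("wrote results/design_power.json\n")
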