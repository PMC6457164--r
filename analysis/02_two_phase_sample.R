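#!/usr/bin/env Rscript
# Phase-two verification sampling: all screen-positives invited, negatives at
# 1:4 for the first half of enrolment then 1:6, thinned by consent; design
# weights from realized interviewed counts per stratum.

suppressPackageStartupMessages(library(twophasedx))
SEED <- 20260102

pop <- load_cohort_csv("results/cohort.csv")
schedule <- data.frame(start = c(1, floor(nrow(pop) / 2) + 1), k = c(4, 6))
pop <- draw_sample(pop, schedule, seed = SEED)
w <- compute_weights(pop)
pop <- apply_design_weights(pop, w)

print(w)
cat(sprintf("invited: %d | interviewed: %d (%d+ / %d-)\n",
            sum(pop$invited), sum(pop$interviewed),
            sum(pop$interviewed & pop$stratum == "positive"),
            sum(pop$interviewed & pop$stratum == "negative")))
cat(sprintf("sum of weights over interviewed = %.1f (frame %d)\n",
            sum(pop$design_weight[pop$interviewed]), nrow(pop)))

write_cohort_csv(pop, "results/cohort_sampled.csv")
jsonlite::write_json(as.data.frame(w), "results/frame_totals.json", digits = NA)
cat("wrote results/cohort_sampled.csv, results/frame_totals.json\n")
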