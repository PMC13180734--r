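#!/usr/bin/env Rscript
# Simulate the synthetic cohort the analysis runs on: 74 infants on ~138
# test occasions at 31-36 weeks PMA, with a latent brain age gap
# (mean 0, SD 0.91 weeks) driving apnoea rate at -0.22 apnoeas/h per week.
# Writes the occasion table and its ground truth under results/.

suppressPackageStartupMessages(library(apnoeagap))
dir.create("results", showWarnings = FALSE)

cohort <- simulate_cohort(cohort_params(seed = 1))
write.csv(cohort$occasions, "results/cohort.csv", row.names = FALSE)
write.csv(cohort$truth, "results/cohort_truth.csv", row.names = FALSE)
write.csv(cohort$post_caffeine, "results/cohort_post_caffeine.csv",
          row.names = FALSE)

cat(sprintf("cohort: %d infants, %d occasions\n",
            length(unique(cohort$occasions$infant_id)),
            nrow(cohort$occasions)))
cat(sprintf("latent gap: mean %.3f, SD %.3f weeks (generator: 0, 0.91)\n",
            mean(cohort$truth$true_gap), sd(cohort$truth$true_gap)))
cat(sprintf("true apnoea rate: %.2f +/- %.2f apnoeas/h\n",
            mean(cohort$truth$true_apnoea_rate),
            sd(cohort$truth$true_apnoea_rate)))
cat(sprintf("%d infants eligible for the post-caffeine sub-study\n",
            nrow(cohort$post_caffeine)))
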