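#!/usr/bin/env Rscript
# Summarise the brain-age stage of the pipeline run (02_pipeline.R):
# model accuracies, availability, the bias-correction identities and the
# maturity split. Writes results/brain_age_summary.csv.

suppressPackageStartupMessages(library(apnoeagap))

gap <- read.csv("results/pipeline/gap.csv")
cohort <- read.csv("results/pipeline/cohort.csv")

summary_tab <- data.frame(
  n_occasions = nrow(gap),
  sensory_available = sum(!is.na(gap$sensory_age)),
  resting_available = sum(!is.na(gap$resting_age)),
  sensory_mae_weeks = mean(abs(gap$sensory_age - gap$pma_weeks), na.rm = TRUE),
  resting_mae_weeks = mean(abs(gap$resting_age - gap$pma_weeks), na.rm = TRUE),
  gap_mean_weeks = mean(gap$corrected_gap),
  gap_sd_weeks = sd(gap$corrected_gap),
  gap_pma_correlation = cor(gap$corrected_gap, gap$pma_weeks),
  pct_mature = 100 * mean(gap$maturity == "mature")
)
write.csv(summary_tab, "results/brain_age_summary.csv", row.names = FALSE)
print(t(round(summary_tab, 4)))
cat("\nNote: cross-fitted predictions shrink towards the cohort mean, so the\n")
cat("estimated gap SD sits below the generating SD of 0.91 weeks; the\n")
cat("bias-corrected gap is exactly centred and uncorrelated with PMA.\n")
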