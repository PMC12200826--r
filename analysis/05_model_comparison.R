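#!/usr/bin/env Rscript
# Stage 5: nested logistic model comparison.
#
# Per EEG channel, fits the three-model ladder for insight —
# baseline (insight ~ stage), full (insight ~ stage + slope), and
# slope-only (insight ~ slope) — and compares them by AIC and
# likelihood-ratio tests, with adjusted McFadden R2 as the overall fit
# measure. On the simulated cohort (where insight truly co-varies with
# the aperiodic exponent beyond stage), the slope-carrying models should
# win on most channels.
#
# Outputs: results/model_comparison.csv

suppressMessages(library(napinsight))

slopes <- read.csv("results/slopes_whole_nap.csv")
labels <- read.csv("results/insight_labels.csv")
labels <- labels[!labels$excluded, ]

ladder <- channelwise_model_comparison(
  slopes,
  stats::setNames(labels$group, labels$subject),
  stats::setNames(labels$is_insight, labels$subject))
utils::write.csv(ladder, "results/model_comparison.csv",
                 row.names = FALSE)

message("Best model per channel:")
print(table(ladder$best_model))
f4 <- ladder[ladder$channel == "F4", ]
message(sprintf(
  "F4: AIC baseline %.1f, full %.1f, slope-only %.1f; slope beta (full) %.2f",
  f4$aic_baseline, f4$aic_full, f4$aic_slope_only, f4$beta_slope_full))
message(sprintf(
  "F4 LRT full vs baseline: X2(1) = %.2f, p = %.3f",
  f4$lrt_full_vs_baseline_X2, f4$lrt_full_vs_baseline_p))
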