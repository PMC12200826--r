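#!/usr/bin/env Rscript
# Stage 2: behavioural inclusion, insight classification, and the
# contingency-table statistics.
#
# Applies the two inclusion filters (>= 80% accuracy on the easy
# coherence levels of block 3; no pre-nap strategy switch), fits the
# four-parameter sigmoid to every kept subject's 5%-coherence series,
# classifies insight by the 85% block-8 criterion, and reproduces the
# group-wise Fisher tests. Also verifies the full set of published
# statistics from the study counts.
#
# Outputs: results/insight_labels.csv, results/contingency_table.csv,
# results/switch_aligned_curve.csv, results/printed_statistics_check.csv

suppressMessages(library(napinsight))

cohort <- readRDS("scratch/cohort.rds")

filt <- apply_inclusion_filters(cohort)
message("Excluded ", sum(filt$log$excluded), " of ", length(cohort),
        " subjects: ",
        paste(names(table(filt$log$reason[filt$log$excluded])),
              collapse = ", "))

labels <- classify_cohort(filt$kept)
tab <- group_insight_table(labels, stats::setNames(labels$group,
                                                   labels$subject))
print(tab)
utils::write.csv(as.data.frame(unclass(tab)),
                 "results/contingency_table.csv")
full_log <- merge(filt$log, labels, by = "subject", all.x = TRUE)
write_insight_labels(full_log, "results/insight_labels.csv")

for (pair in list(c("N2", "Wake"), c("N1", "Wake"), c("N1", "N2"))) {
  ft <- fisher_exact_2x2(tab[pair, ])
  message(sprintf("Fisher %s vs %s: p = %.3f (OR %.2f)",
                  pair[1], pair[2], ft$p, ft$odds_ratio))
}

aligned <- switch_aligned_summary(filt$kept, labels)
utils::write.csv(aligned$curve, "results/switch_aligned_curve.csv",
                 row.names = FALSE)
message(sprintf("Switch-aligned jump: %.3f (pre %.1f%%, post %.1f%%, %d subjects)",
                aligned$jump, 100 * aligned$pre_mean,
                100 * aligned$post_mean, aligned$n_subjects))

v <- verify_printed_statistics()
utils::write.csv(v, "results/printed_statistics_check.csv",
                 row.names = FALSE)
message("Printed-statistics check: ", sum(v$pass), "/", nrow(v), " pass")
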