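#!/usr/bin/env Rscript
# Stage 3: spectral slopes.
#
# For every included subject, computes the averaged power spectrum of
# the whole 20-minute nap (6-s epochs, 50% overlap, Hanning, 1-45 Hz at
# 0.2 Hz), decomposes it into aperiodic and oscillatory components with
# the knee fixed at zero, and tabulates the spectral slope (-x) per
# channel. The deepest-stage variant restricts the epochs to each
# subject's deepest sleep stage. Also writes the flattened (aperiodic-
# corrected) spectra over 1-20 Hz used by the cluster tests.
#
# Outputs: results/slopes_whole_nap.csv, results/slopes_deepest_stage.csv,
# scratch/flattened_spectra.csv

suppressMessages(library(napinsight))

cohort <- readRDS("scratch/cohort.rds")
keep <- read.csv("results/insight_labels.csv")
kept_ids <- keep$subject[!keep$excluded]
cohort <- structure(cohort[vapply(cohort, `[[`, "", "id") %in% kept_ids],
                    class = "nap_cohort")

message("Fitting spectral slopes (whole nap)...")
slopes <- slope_per_subject(cohort, provenance = "whole-nap")
write_slope_table(slopes, "results/slopes_whole_nap.csv")
print(round(tapply(slopes$slope, slopes$group, mean), 3))

message("Fitting spectral slopes (deepest stage)...")
deep <- slope_per_subject(cohort, provenance = "deepest-stage")
write_slope_table(deep, "results/slopes_deepest_stage.csv")
print(round(tapply(deep$slope, deep$group, mean, na.rm = TRUE), 3))

message("Flattening spectra (1-20 Hz residuals)...")
rows <- list()
for (s in cohort) {
  spec <- compute_psd(epoch_signal(s$recording))
  for (ch in seq_along(spec$channel_names)) {
    fit <- fit_spectral_model(spec$frequencies, spec$power[ch, ])
    flat <- flatten_spectrum(spec$frequencies, spec$power[ch, ], fit)
    rows[[length(rows) + 1L]] <- data.frame(
      subject = s$id, group = s$group,
      channel = spec$channel_names[ch],
      frequency = flat$frequency, residual = flat$residual)
  }
}
flat_tab <- do.call(rbind, rows)
utils::write.csv(flat_tab, "scratch/flattened_spectra.csv",
                 row.names = FALSE)
message("Wrote ", nrow(flat_tab), " flattened-spectrum rows for ",
        length(cohort), " subjects.")
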