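#!/usr/bin/env Rscript
# Stage 4: cluster-based permutation tests.
#
# (a) Stage contrast of oscillatory activity: one-way F statistics over
#     channels x 1-20 Hz bins of the flattened spectra (Wake/N1/N2,
#     1000 permutations, alpha 0.05, cluster alpha 0.05), with post-hoc
#     pairwise t contrasts.
# (b) Insight contrast of aperiodic activity: Welch t statistics over
#     the channel-wise spectral slopes of insight vs no-insight
#     subjects (1000 permutations, alpha 0.025).
#
# Outputs: results/cluster_stage_oscillatory.json,
# results/cluster_insight_slope.json

suppressMessages(library(napinsight))

SEED <- 20250104
flat <- read.csv("scratch/flattened_spectra.csv")
labels <- read.csv("results/insight_labels.csv")
labels <- labels[!labels$excluded, ]

mont <- default_montage()
adj <- build_adjacency(mont)
freqs <- sort(unique(flat$frequency))
subjects <- unique(flat$subject)
data <- array(NA_real_, c(length(subjects), nrow(mont), length(freqs)))
for (i in seq_along(subjects)) {
  d <- flat[flat$subject == subjects[i], ]
  for (ch in seq_len(nrow(mont))) {
    data[i, ch, ] <- d$residual[d$channel == mont$channel[ch]][
      order(d$frequency[d$channel == mont$channel[ch]])]
  }
}
groups <- flat$group[match(subjects, flat$subject)]

message("Stage contrast (F) on flattened spectra...")
rF <- cluster_permutation_test(data, groups, "F", adj, n_perm = 1000,
                               alpha = 0.05, cluster_alpha = 0.05,
                               seed = SEED)
print(rF)
if (nrow(rF$clusters)) {
  rng <- range(freqs[rF$members[[1]]$bin])
  message(sprintf("Top F cluster spans %.1f-%.1f Hz (p = %.3f)",
                  rng[1], rng[2], rF$clusters$p[1]))
}

ph <- posthoc_pairwise(data, groups,
                       list(c("Wake", "N1"), c("Wake", "N2"),
                            c("N1", "N2")),
                       adjacency = adj, n_perm = 1000, seed = SEED + 1)
summ <- lapply(ph, function(r) r$clusters)
for (nm in names(ph)) {
  cl <- ph[[nm]]$clusters
  if (nrow(cl)) {
    rng <- range(freqs[ph[[nm]]$members[[1]]$bin])
    message(sprintf("%s: %s cluster %.1f-%.1f Hz, p = %.3f", nm,
                    cl$sign[1], rng[1], rng[2], cl$p[1]))
  } else message(nm, ": no clusters")
}
jsonlite::write_json(list(stage_F = rF$clusters, posthoc = summ),
                     "results/cluster_stage_oscillatory.json",
                     auto_unbox = TRUE, digits = NA)

message("Insight contrast (t) on channel-wise slopes...")
slopes <- read.csv("results/slopes_whole_nap.csv")
wide <- stats::reshape(slopes[, c("subject", "channel", "slope")],
                       idvar = "subject", timevar = "channel",
                       direction = "wide")
mat <- as.matrix(wide[, paste0("slope.", mont$channel)])
ins <- labels$is_insight[match(wide$subject, labels$subject)]
rT <- cluster_permutation_test(mat, ifelse(ins, "insight", "no_insight"),
                               "t", adj, n_perm = 1000, alpha = 0.025,
                               cluster_alpha = 0.05, seed = SEED + 2)
print(rT)
if (nrow(rT$clusters)) {
  message("Channels in the top insight cluster: ",
          paste(rT$members[[1]]$channel, collapse = ", "))
}
jsonlite::write_json(rT$clusters, "results/cluster_insight_slope.json",
                     auto_unbox = TRUE, digits = NA)
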