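#' Published study counts used as a verification fixture
#'
#' Insight / no-insight counts per nap group for the 68-subject study
#' sample (N2 24/4, N1 14/8, Wake 10/8), the no-delay baseline cohort
#' (49 of 99 with insight), and the N2 group after excluding naps with
#' under two minutes of N2 sleep (21/3).
#' @return named list of integer vectors c(insight, no_insight).
#' @export
insight_study_counts <- function() {
  list(
    N2 = c(insight = 24L, no_insight = 4L),
    N1 = c(insight = 14L, no_insight = 8L),
    Wake = c(insight = 10L, no_insight = 8L),
    baseline_nodelay = c(insight = 49L, no_insight = 50L),
    N2_adjusted = c(insight = 21L, no_insight = 3L)
  )
}

#' Expand per-group counts to a subject-level outcome table
#' @param counts named list of c(insight, no_insight) per group
#'   (groups among Wake/N1/N2).
#' @keywords internal
counts_to_outcomes <- function(counts) {
  groups <- intersect(c("Wake", "N1", "N2"), names(counts))
  do.call(rbind, lapply(groups, function(g) {
    data.frame(
      stage = g,
      insight = rep(c(TRUE, FALSE), times = counts[[g]]),
      stringsAsFactors = FALSE
    )
  }))
}

#' Recompute the headline statistics from the published counts
#'
#' Runs the package's own Fisher, logistic-model and likelihood-ratio
#' machinery on the fixed study counts and compares each quantity with
#' its published value at the published precision.
#'
#' @param counts count fixture, by default [insight_study_counts()].
#' @return data.frame: `quantity`, `computed`, `printed`, `digits`,
#'   `pass`.
#' @export
verify_printed_statistics <- function(counts = insight_study_counts()) {
  if (length(counts) == 0) stop("empty count fixture")
  need <- c("N2", "N1", "Wake", "baseline_nodelay", "N2_adjusted")
  if (!all(need %in% names(counts))) {
    stop("count fixture missing group(s): ",
         paste(setdiff(need, names(counts)), collapse = ", "))
  }
  tab <- function(a, b) rbind(counts[[a]], counts[[b]])
  overall <- c(insight = sum(vapply(counts[c("N2", "N1", "Wake")],
                                    `[[`, 0L, "insight")),
               no_insight = sum(vapply(counts[c("N2", "N1", "Wake")],
                                       `[[`, 0L, "no_insight")))
  d <- counts_to_outcomes(counts)
  m0 <- fit_logistic(insight ~ 1, d)
  m1 <- fit_logistic(insight ~ stage, d)
  lrt <- likelihood_ratio_test(m0, m1)
  cf <- m1$coefficients
  beta <- function(term, what = "estimate") cf[[what]][cf$term == term]
  rows <- list(
    list("fisher_p_n2_vs_wake", fisher_exact_2x2(tab("N2", "Wake"))$p, 0.038, 3),
    list("fisher_p_n1_vs_wake", fisher_exact_2x2(tab("N1", "Wake"))$p, 0.75, 2),
    list("fisher_p_n1_vs_n2", fisher_exact_2x2(tab("N1", "N2"))$p, 0.1, 1),
    list("fisher_p_postnap_vs_baseline",
         fisher_exact_2x2(rbind(overall, counts$baseline_nodelay))$p, 0.007, 3),
    list("fisher_p_n2adj_vs_wake",
         fisher_exact_2x2(tab("N2_adjusted", "Wake"))$p, 0.03, 2),
    list("aic_null", m0$AIC, 84.4, 1),
    list("aic_stage", m1$AIC, 82.5, 1),
    list("lrt_x2", lrt$X2, 5.85, 2),
    list("lrt_p", lrt$p, 0.05, 2),
    list("beta_n1_vs_wake", beta("stageN1"), 0.34, 2),
    list("beta_n2_vs_wake", beta("stageN2"), 1.57, 2),
    list("wald_p_n2_vs_wake", beta("stageN2", "p"), 0.03, 2),
    list("wald_p_n1_vs_wake", beta("stageN1", "p"), 0.6, 1)
  )
  out <- do.call(rbind, lapply(rows, function(r) {
    data.frame(quantity = r[[1]], computed = r[[2]], printed = r[[3]],
               digits = r[[4]],
               pass = round(r[[2]], r[[4]]) == r[[3]],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Run the full simulation-and-inference pipeline
#'
#' Executes, in order: cohort simulation, behavioural inclusion and
#' insight classification, (optionally) spectral slope estimation and
#' cluster tests, and the contingency/model-comparison inference layer.
#' Stage outputs are written under `cfg$outdir` as CSV/JSON and a run
#' manifest with per-stage wall-clock and output checksums is returned
#' and saved.
#'
#' @param cfg a `run_config` (see [read_run_config()]) or a list of
#'   overrides for its defaults.
#' @return list of class `run_manifest`: `config`, `stages` (per stage:
#'   seconds, outputs, md5), `report` (key results).
#' @export
run_pipeline <- function(cfg = list()) {
  if (!inherits(cfg, "run_config")) {
    tmp <- tempfile(fileext = ".yaml")
    yaml::write_yaml(cfg, tmp)
    cfg <- read_run_config(tmp)
    unlink(tmp)
  }
  if (any(c(cfg$n_wake, cfg$n_n1, cfg$n_n2) <= 0)) {
    stop("validation: all group sizes must be positive")
  }
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = unclass(cfg), stages = list())
  report <- list()
  run_stage <- function(name, f) {
    t0 <- Sys.time()
    out_files <- tryCatch(f(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")),
      outputs = out_files,
      md5 = if (length(out_files)) unname(tools::md5sum(out_files))
            else character(0)
    )
  }

  cohort <- NULL
  run_stage("simulate", function() {
    cohort <<- simulate_cohort(
      n_per_group = c(N2 = cfg$n_n2, N1 = cfg$n_n1, Wake = cfg$n_wake),
      insight_rates = c(N2 = cfg$rate_n2, N1 = cfg$rate_n1,
                        Wake = cfg$rate_wake),
      seed = cfg$seed, quota = cfg$quota,
      include_eeg = cfg$include_eeg,
      slope_coupling = cfg$slope_coupling)
    truth_path <- file.path(cfg$outdir, "cohort_truth.csv")
    utils::write.csv(cohort_truth(cohort), truth_path, row.names = FALSE)
    truth_path
  })

  labels <- NULL
  run_stage("behavior", function() {
    filt <- apply_inclusion_filters(cohort)
    labels <<- classify_cohort(filt$kept)
    tab <- group_insight_table(labels, stats::setNames(labels$group,
                                                       labels$subject))
    aligned <- tryCatch(switch_aligned_summary(filt$kept, labels),
                        error = function(e) NULL)
    report$contingency_table <<- tab
    report$fisher <<- list(
      n2_vs_wake = fisher_exact_2x2(tab[c("N2", "Wake"), ])$p,
      n1_vs_wake = fisher_exact_2x2(tab[c("N1", "Wake"), ])$p,
      n1_vs_n2 = fisher_exact_2x2(tab[c("N1", "N2"), ])$p)
    report$jump <<- if (is.null(aligned)) NA_real_ else aligned$jump
    report$n_excluded <<- sum(filt$log$excluded)
    lab_path <- file.path(cfg$outdir, "insight_labels.csv")
    full_log <- merge(filt$log, labels, by = "subject", all.x = TRUE)
    write_insight_labels(full_log, lab_path)
    tab_path <- file.path(cfg$outdir, "contingency_table.csv")
    utils::write.csv(as.data.frame(unclass(tab)), tab_path)
    curve_path <- file.path(cfg$outdir, "switch_aligned_curve.csv")
    if (!is.null(aligned)) {
      utils::write.csv(aligned$curve, curve_path, row.names = FALSE)
    }
    c(lab_path, tab_path,
      if (!is.null(aligned)) curve_path else character(0))
  })

  slopes <- NULL
  if (cfg$include_eeg) {
    run_stage("spectra", function() {
      slopes <<- slope_per_subject(cohort)
      # keep only subjects that passed inclusion
      slopes <<- slopes[slopes$subject %in% labels$subject, ]
      slope_path <- file.path(cfg$outdir, "slopes.csv")
      write_slope_table(slopes, slope_path)
      slope_path
    })
    run_stage("clusters", function() {
      wide <- stats::reshape(
        slopes[, c("subject", "channel", "slope")],
        idvar = "subject", timevar = "channel", direction = "wide")
      mat <- as.matrix(wide[, -1])
      colnames(mat) <- sub("^slope\\.", "", colnames(mat))
      montage <- default_montage()
      mat <- mat[, montage$channel, drop = FALSE]
      adj <- build_adjacency(montage)
      grp <- stats::setNames(labels$group, labels$subject)[wide$subject]
      ins <- stats::setNames(labels$is_insight,
                             labels$subject)[wide$subject]
      stage_test <- cluster_permutation_test(
        mat, grp, stat = "F", adjacency = adj,
        n_perm = cfg$n_permutations, alpha = cfg$alpha,
        cluster_alpha = cfg$cluster_alpha,
        seed = derive_seed(cfg$seed, 901L))
      insight_test <- cluster_permutation_test(
        mat, ifelse(ins, "insight", "no_insight"), stat = "t",
        adjacency = adj, n_perm = cfg$n_permutations, alpha = 0.025,
        cluster_alpha = cfg$cluster_alpha,
        seed = derive_seed(cfg$seed, 902L))
      report$slope_stage_cluster_p <<-
        if (nrow(stage_test$clusters)) min(stage_test$clusters$p) else NA_real_
      report$slope_insight_cluster_p <<-
        if (nrow(insight_test$clusters)) min(insight_test$clusters$p) else NA_real_
      cl_path <- file.path(cfg$outdir, "slope_cluster_tests.json")
      jsonlite::write_json(
        list(stage_F = stage_test$clusters,
             insight_t = insight_test$clusters),
        cl_path, auto_unbox = TRUE, digits = NA)
      cl_path
    })
  }

  run_stage("infer", function() {
    d <- data.frame(stage = labels$group, insight = labels$is_insight,
                    stringsAsFactors = FALSE)
    m0 <- fit_logistic(insight ~ 1, d)
    m1 <- fit_logistic(insight ~ stage, d)
    report$aic_null <<- m0$AIC
    report$aic_stage <<- m1$AIC
    report$lrt_stage <<- unclass(likelihood_ratio_test(m0, m1))
    out <- character(0)
    if (!is.null(slopes)) {
      ladder <- channelwise_model_comparison(
        slopes,
        stats::setNames(labels$group, labels$subject),
        stats::setNames(labels$is_insight, labels$subject))
      report$model_ladder <<- ladder
      ladder_path <- file.path(cfg$outdir, "model_comparison.csv")
      utils::write.csv(ladder, ladder_path, row.names = FALSE)
      out <- ladder_path
    }
    report_path <- file.path(cfg$outdir, "report.json")
    jsonlite::write_json(report, report_path, auto_unbox = TRUE,
                         digits = NA, force = TRUE)
    c(out, report_path)
  })

  manifest$report <- report
  structure(manifest, class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("Pipeline run (seed", x$config$seed, ")\n")
  for (nm in names(x$stages)) {
    cat(sprintf("  %-10s %6.2f s  %d output(s)\n", nm,
                x$stages[[nm]]$seconds, length(x$stages[[nm]]$outputs)))
  }
  if (!is.null(x$report$contingency_table)) {
    print(x$report$contingency_table)
  }
  invisible(x)
}
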