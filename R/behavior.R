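#' Accuracy threshold of the behavioural inclusion filter
#' @keywords internal
INCLUSION_ACC_THRESHOLD <- 0.80

#' Insight classification threshold (accuracy on hardest trials,
#' last pre-instruction block)
#' @keywords internal
INSIGHT_ACC_THRESHOLD <- 0.85

# Easy-coherence accuracy in the last fully uncorrelated block (block 3).
.passes_accuracy_filter <- function(session) {
  sel <- session$block == 3L & session$coherence %in% c(0.41, 0.59, 0.76)
  mean(session$correct[sel]) >= INCLUSION_ACC_THRESHOLD
}

# Pre-nap performance on the hardest trials after colour onset
# (trials 351-400): "classifier-positive" if above the insight threshold.
.prenap_positive <- function(session) {
  sel <- session$trial >= COLOUR_ONSET_TRIAL &
    session$trial <= NAP_BOUNDARY_TRIAL & session$coherence == 0.05
  sum(sel) > 0 && mean(session$correct[sel]) > INSIGHT_ACC_THRESHOLD
}

# Exclusion reason for one session: "low-accuracy", "pre-nap-insight"
# or "none". The sigmoid fit is only computed when pre-nap performance
# is already classifier-positive.
.exclusion_reason <- function(session) {
  if (!.passes_accuracy_filter(session)) return("low-accuracy")
  if (.prenap_positive(session)) {
    fit <- fit_sigmoid_session(session)
    if (fit$t_s < NAP_BOUNDARY_TRIAL) return("pre-nap-insight")
  }
  "none"
}

#' Apply behavioural inclusion filters to a cohort
#'
#' Two exclusion rules: (1) subjects below 80% accuracy on the three
#' easiest coherence levels (41/59/76%) in the last fully uncorrelated
#' block (block 3) are excluded for not having learned the motion
#' classification; (2) subjects who already switched to the colour
#' strategy before the nap — classifier-positive accuracy on the hardest
#' trials between colour onset and the nap, with a fitted switch point
#' before the nap boundary — are excluded as pre-nap insight.
#'
#' @param cohort a `nap_cohort` (or plain list of subjects with
#'   `$session`).
#' @return list with `kept` (filtered cohort, class preserved) and
#'   `log` (data.frame subject, excluded, reason).
#' @export
apply_inclusion_filters <- function(cohort) {
  if (length(cohort) == 0) stop("empty cohort")
  reasons <- vapply(cohort, function(s) .exclusion_reason(s$session),
                    character(1))
  keep <- reasons == "none"
  kept <- cohort[keep]
  class(kept) <- class(cohort)
  list(
    kept = kept,
    log = data.frame(
      subject = vapply(cohort, `[[`, character(1), "id"),
      excluded = !keep,
      reason = reasons,
      stringsAsFactors = FALSE
    )
  )
}

# Negative Bernoulli log-likelihood of the 4-parameter sigmoid.
# Parameterised as (y_min, dy, m, t_s) with y_max = y_min + dy*(1 - y_min)
# so the box constraint dy in [0,1] enforces y_min <= y_max <= 1.
.sigmoid_nll <- function(par, correct, trials) {
  y_min <- par[1]
  y_max <- y_min + par[2] * (1 - y_min)
  p <- y_min + (y_max - y_min) / (1 + exp(-par[3] * (trials - par[4])))
  p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
  -sum(ifelse(correct, log(p), log1p(-p)))
}

#' Fit the four-parameter sigmoid change-point model
#'
#' Maximises the Bernoulli likelihood of
#' y(t) = y_min + (y_max - y_min) / (1 + exp(-m (t - t_s)))
#' over bounded parameters (0 <= y_min <= y_max <= 1, 0 <= m <= 10,
#' t_s inside the fitted trial range), using a multi-start strategy with
#' switch-point starts every `grid_step` trials refined by L-BFGS-B.
#' Ties between equally likely optima are broken towards the smallest
#' switch point.
#'
#' @param correct logical (or 0/1) vector of trial outcomes.
#' @param trials trial positions of the outcomes (same length).
#' @param grid_step spacing (trials) of the switch-point starting grid.
#' @return list of class `sigmoid_fit`: `y_min`, `y_max`, `m`, `t_s`,
#'   `logLik`, `converged`, `n`.
#' @export
fit_sigmoid <- function(correct, trials, grid_step = 10) {
  correct <- as.logical(correct)
  stopifnot(length(correct) == length(trials), !anyNA(correct))
  if (length(correct) < 30) stop("need at least 30 trials to fit")
  lo <- c(0, 0, 0, min(trials))
  hi <- c(1, 1, 10, max(trials))
  starts <- seq(min(trials), max(trials), by = grid_step)
  pre_rate <- function(ts) {
    r <- mean(correct[trials <= ts])
    if (is.nan(r)) mean(correct) else r
  }
  post_rate <- function(ts) {
    r <- mean(correct[trials > ts])
    if (is.nan(r)) mean(correct) else r
  }
  # score every grid start with plug-in rate estimates, then refine the
  # most promising ones by bounded quasi-Newton
  start_pars <- lapply(starts, function(ts0) {
    y0 <- min(max(pre_rate(ts0), 0.01), 0.99)
    y1 <- min(max(post_rate(ts0), 0.01), 0.99)
    dy0 <- min(max((y1 - y0) / (1 - y0), 0.01), 0.99)
    c(y0, dy0, 0.5, ts0)
  })
  start_nll <- vapply(start_pars, .sigmoid_nll, numeric(1),
                      correct = correct, trials = trials)
  refine <- order(start_nll)[seq_len(min(5L, length(starts)))]
  best <- NULL
  converged <- FALSE
  for (r in refine) {
    for (m0 in c(0.03, 0.1, 0.5)) {
      par0 <- start_pars[[r]]
      par0[3] <- m0
      opt <- tryCatch(
        stats::optim(par0, .sigmoid_nll, correct = correct,
                     trials = trials, method = "L-BFGS-B",
                     lower = lo, upper = hi),
        error = function(e) NULL
      )
      if (is.null(opt)) next
      if (opt$convergence == 0) converged <- TRUE
      better <- is.null(best) ||
        opt$value < best$value - 1e-8 ||
        (abs(opt$value - best$value) <= 1e-8 && opt$par[4] < best$par[4])
      if (better) best <- opt
    }
  }
  if (is.null(best)) {
    # best effort: report the flat fit at the empirical rate
    r <- min(max(mean(correct), 1e-6), 1 - 1e-6)
    best <- list(par = c(r, 0, 0, min(trials)),
                 value = .sigmoid_nll(c(r, 0, 0, min(trials)),
                                      correct, trials))
    converged <- FALSE
  }
  p <- best$par
  structure(
    list(y_min = p[1], y_max = p[1] + p[2] * (1 - p[1]),
         m = p[3], t_s = p[4],
         logLik = -best$value, converged = converged,
         n = length(correct)),
    class = "sigmoid_fit"
  )
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf(
    "Sigmoid fit: y_min=%.3f y_max=%.3f m=%.3f t_s=%.1f (logLik %.2f, %s)\n",
    x$y_min, x$y_max, x$m, x$t_s, x$logLik,
    if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Fit the sigmoid to a session's hardest (5% coherence) trials
#'
#' Uses the non-instructed trials of the full-noise phase (blocks 3-8).
#' @param session a `session_data`.
#' @param ... passed to [fit_sigmoid()].
#' @export
fit_sigmoid_session <- function(session, ...) {
  sel <- session$coherence == 0.05 & session$block >= 3L &
    session$block < INSTRUCTION_BLOCK
  fit_sigmoid(session$correct[sel], session$trial[sel], ...)
}

#' Classify a subject as insight vs. no-insight
#'
#' A subject counts as having gained insight if accuracy on the hardest
#' (5% coherence) trials in the last task block before the colour rule
#' was instructed (block 8) exceeds 85%. The switch point is taken from
#' the sigmoid fit (midpoint t_s) for insight subjects.
#'
#' @param session a `session_data` that passed inclusion.
#' @param fit the subject's `sigmoid_fit`.
#' @param subject optional subject id.
#' @return data.frame row: `subject`, `is_insight`, `t_s`.
#' @export
classify_insight <- function(session, fit, subject = NA_character_) {
  sel <- session$block == INSTRUCTION_BLOCK - 1L & session$coherence == 0.05
  acc <- mean(session$correct[sel])
  is_insight <- acc > INSIGHT_ACC_THRESHOLD
  data.frame(subject = subject, is_insight = is_insight,
             t_s = if (is_insight) fit$t_s else NA_real_,
             block8_acc = acc, stringsAsFactors = FALSE)
}

#' Classify every subject of a cohort
#'
#' Convenience wrapper: sigmoid fit plus threshold classification per
#' subject.
#' @param cohort a `nap_cohort`.
#' @param ... passed to [fit_sigmoid_session()].
#' @return data.frame with one row per subject (`subject`, `group`,
#'   `is_insight`, `t_s`, `block8_acc`).
#' @export
classify_cohort <- function(cohort, ...) {
  rows <- lapply(cohort, function(s) {
    fit <- fit_sigmoid_session(s$session, ...)
    out <- classify_insight(s$session, fit, subject = s$id)
    out$group <- s$group
    out
  })
  do.call(rbind, rows)[, c("subject", "group", "is_insight", "t_s",
                           "block8_acc")]
}

#' Switch-aligned accuracy/RT curves and the performance jump
#'
#' Aligns each insight subject's hardest-coherence (5%) trial series to
#' their fitted switch point and summarises accuracy and reaction time
#' as a function of position within that series. Positions count trials
#' of the 5%-coherence series itself (the trials on which the switch is
#' measured), so a 15-trial window holds 15 hard trials. The jump
#' statistic is the mean (across subjects) difference between
#' post-switch and pre-switch window accuracy.
#'
#' @param cohort a `nap_cohort` (or list of subjects with `$session`).
#' @param labels classification table from [classify_cohort()] (needs
#'   `subject`, `is_insight`, `t_s`).
#' @param window_trials half-window width, in hard trials.
#' @return list: `curve` (data.frame rel_trial, accuracy, rt_ms, n),
#'   `jump`, `pre_mean`, `post_mean`, `n_subjects`.
#' @export
switch_aligned_summary <- function(cohort, labels, window_trials = 15) {
  ins <- labels[labels$is_insight & !is.na(labels$t_s), , drop = FALSE]
  if (nrow(ins) == 0) stop("no insight subjects to align")
  ids <- vapply(cohort, `[[`, character(1), "id")
  rel_all <- acc_all <- rt_all <- numeric(0)
  pre <- post <- numeric(0)
  for (j in seq_len(nrow(ins))) {
    s <- cohort[[match(ins$subject[j], ids)]]
    sel <- which(s$session$coherence == 0.05 &
                   !s$session$block %in% INSTRUCTION_BLOCK)
    sel <- sel[order(s$session$trial[sel])]
    corr <- s$session$correct[sel]
    rts <- s$session$rt_ms[sel]
    # position within the hard-trial series relative to the switch:
    # the first hard trial after t_s has rel = +1
    n_before <- sum(s$session$trial[sel] <= ins$t_s[j])
    rel <- seq_along(sel) - n_before
    rel[rel <= 0] <- rel[rel <= 0] - 1L # .. and the last before has -1
    rel_all <- c(rel_all, rel)
    acc_all <- c(acc_all, corr)
    rt_all <- c(rt_all, rts)
    pre_sel <- rel >= -window_trials & rel <= -1
    post_sel <- rel >= 1 & rel <= window_trials
    if (sum(pre_sel) < window_trials || sum(post_sel) < window_trials) {
      warning("window truncated for subject ", ins$subject[j])
    }
    pre <- c(pre, mean(corr[pre_sel]))
    post <- c(post, mean(corr[post_sel]))
  }
  curve <- do.call(rbind, lapply(split(seq_along(rel_all), rel_all),
                                 function(ix) {
    data.frame(rel_trial = rel_all[ix[1]], accuracy = mean(acc_all[ix]),
               rt_ms = mean(rt_all[ix]), n = length(ix))
  }))
  curve <- curve[order(curve$rel_trial), ]
  rownames(curve) <- NULL
  list(curve = curve,
       jump = mean(post, na.rm = TRUE) - mean(pre, na.rm = TRUE),
       pre_mean = mean(pre, na.rm = TRUE),
       post_mean = mean(post, na.rm = TRUE),
       n_subjects = nrow(ins))
}

#' Insight-by-group contingency table
#'
#' @param labels data.frame with `subject` and `is_insight`.
#' @param groups named character vector (names = subject ids) or a
#'   data.frame with `subject` and `group`.
#' @param group_order row order of the table.
#' @return integer matrix (groups x insight/no_insight) of class
#'   `contingency_table`.
#' @export
group_insight_table <- function(labels, groups,
                                group_order = c("N2", "N1", "Wake")) {
  if (nrow(labels) == 0) stop("empty label list")
  if (is.data.frame(groups)) {
    groups <- stats::setNames(groups$group, groups$subject)
  }
  g <- groups[labels$subject]
  if (anyNA(g)) stop("subject(s) without a group label")
  if (!all(g %in% group_order)) {
    stop("unknown group label(s): ",
         paste(setdiff(unique(g), group_order), collapse = ", "))
  }
  tab <- vapply(group_order, function(grp) {
    sel <- g == grp
    c(insight = sum(labels$is_insight[sel]),
      no_insight = sum(!labels$is_insight[sel]))
  }, integer(2))
  out <- t(tab)
  class(out) <- c("contingency_table", class(out))
  out
}

#' @export
print.contingency_table <- function(x, ...) {
  print(unclass(x))
  invisible(x)
}
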