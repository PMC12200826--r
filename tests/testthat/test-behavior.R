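test_that("sigmoid recovery on step-like series", {
  errs <- vapply(1:25, function(i) {
    ser <- sigmoid_series(0.5, 1.0, m = 20, t_s = 450, seed = 300 + i)
    fit <- fit_sigmoid(ser$correct, ser$positions)
    fit$t_s - 450
  }, numeric(1))
  expect_lt(median(abs(errs)), 20)
})

test_that("constant all-correct series gives a degenerate but flagged fit", {
  fit <- fit_sigmoid(rep(TRUE, 60), seq(10, 600, 10))
  expect_true(fit$converged)
  expect_lt(abs(fit$y_max - fit$y_min), 0.05)
  expect_gt(fit$y_max, 0.95)
})

test_that("fit refuses series under 30 trials", {
  expect_error(fit_sigmoid(rep(TRUE, 10), 1:10), "at least 30")
})

test_that("likelihood at the optimum beats every grid start", {
  ser <- sigmoid_series(0.56, 0.95, m = 0.3, t_s = 500, seed = 17)
  fit <- fit_sigmoid(ser$correct, ser$positions)
  # recompute the plug-in start likelihoods the fitter uses
  starts <- seq(min(ser$positions), max(ser$positions), by = 10)
  for (ts0 in starts) {
    pre <- mean(ser$correct[ser$positions <= ts0])
    post <- mean(ser$correct[ser$positions > ts0])
    if (is.nan(pre)) pre <- mean(ser$correct)
    if (is.nan(post)) post <- mean(ser$correct)
    y0 <- min(max(pre, 0.01), 0.99)
    dy0 <- min(max((post - y0) / (1 - y0), 0.01), 0.99)
    nll0 <- napinsight:::.sigmoid_nll(c(y0, dy0, 0.5, ts0),
                                      ser$correct, ser$positions)
    expect_gte(nll0, -fit$logLik - 1e-6)
  }
})

test_that("insight classification applies the 85% block-8 criterion", {
  sched <- generate_task_schedule(seed = 6)
  sess <- simulate_agent_responses(sched, agent_params(FALSE), seed = 1)
  hard8 <- which(sess$block == 8 & sess$coherence == 0.05)
  expect_length(hard8, 30)
  fit <- list(t_s = 520)
  class(fit) <- "sigmoid_fit"
  # 26/30 = 0.867 -> insight
  sess$correct[hard8] <- rep(c(TRUE, FALSE), c(26, 4))
  lab <- classify_insight(sess, fit, "a")
  expect_true(lab$is_insight)
  expect_equal(lab$t_s, 520)
  # 25/30 = 0.833 -> no insight
  sess$correct[hard8] <- rep(c(TRUE, FALSE), c(25, 5))
  lab <- classify_insight(sess, fit, "a")
  expect_false(lab$is_insight)
  expect_true(is.na(lab$t_s))
})

test_that("classification ignores RTs and other coherence levels", {
  sched <- generate_task_schedule(seed = 6)
  sess <- simulate_agent_responses(sched, agent_params(FALSE), seed = 3)
  fit <- fit_sigmoid_session(sess)
  base <- classify_insight(sess, fit, "a")
  mutant <- sess
  mutant$rt_ms <- mutant$rt_ms * 10
  other <- mutant$coherence != 0.05
  mutant$correct[other] <- !mutant$correct[other]
  expect_equal(classify_insight(mutant, fit, "a")$is_insight,
               base$is_insight)
})

test_that("inclusion filters catch low accuracy and pre-nap switches", {
  sched <- generate_task_schedule(seed = 8)
  good <- simulate_agent_responses(sched, agent_params(FALSE), seed = 1)
  # low accuracy: wreck the easy trials of block 3
  low <- simulate_agent_responses(sched, agent_params(FALSE), seed = 2)
  easy3 <- low$block == 3 & low$coherence %in% c(0.41, 0.59, 0.76)
  low$correct[easy3] <- rep(c(TRUE, FALSE), length.out = sum(easy3)) # 50%
  # pre-nap switch: perfect performance from colour onset
  pre <- simulate_agent_responses(sched, agent_params(FALSE), seed = 3)
  pre$correct[pre$trial >= 351] <- TRUE
  cohort <- list(list(id = "good", session = good),
                 list(id = "low", session = low),
                 list(id = "pre", session = pre))
  res <- apply_inclusion_filters(cohort)
  expect_equal(res$log$reason, c("none", "low-accuracy", "pre-nap-insight"))
  expect_equal(vapply(res$kept, `[[`, character(1), "id"), "good")
  expect_error(apply_inclusion_filters(list()), "empty cohort")
})

test_that("exclusion boundary sits exactly at 80% easy-trial accuracy", {
  sched <- generate_task_schedule(seed = 8)
  sess <- simulate_agent_responses(sched, agent_params(FALSE), seed = 4)
  easy3 <- which(sess$block == 3 & sess$coherence %in% c(0.41, 0.59, 0.76))
  n <- length(easy3)
  k80 <- ceiling(0.8 * n)
  sess$correct[easy3] <- rep(c(TRUE, FALSE), c(k80, n - k80))
  expect_true(napinsight:::.passes_accuracy_filter(sess))
  sess$correct[easy3] <- rep(c(TRUE, FALSE), c(k80 - 1, n - k80 + 1))
  expect_false(napinsight:::.passes_accuracy_filter(sess))
})

test_that("ground-truth exclusions are recovered on a simulated cohort", {
  cohort <- simulate_cohort(c(N2 = 6, N1 = 5, Wake = 4), seed = 21)
  res <- apply_inclusion_filters(cohort)
  # by construction agents switch after the nap and learn the motion
  # rule; verify the log agrees with a direct recomputation
  for (i in seq_along(cohort)) {
    expected <- if (!napinsight:::.passes_accuracy_filter(cohort[[i]]$session))
      "low-accuracy" else "none"
    if (expected == "none" &&
        napinsight:::.prenap_positive(cohort[[i]]$session)) {
      next # fitted arbitration, exercised in the trio test above
    }
    expect_equal(res$log$reason[i], expected)
  }
})

test_that("switch-aligned jump matches construction for step agents", {
  sched <- generate_task_schedule(seed = 10)
  cohort <- list()
  labels <- NULL
  for (i in 1:40) {
    ag <- agent_params(TRUE, t_s_true = 450 + 10 * (i %% 5), m_true = 10,
                       p_colour = 0.98, lapse = 0)
    sess <- simulate_agent_responses(sched, ag, seed = 400 + i)
    cohort[[i]] <- list(id = paste0("s", i), session = sess)
    labels <- rbind(labels, data.frame(subject = paste0("s", i),
                                       is_insight = TRUE,
                                       t_s = ag$t_s_true))
  }
  al <- switch_aligned_summary(cohort, labels)
  expect_lt(abs(al$jump - 0.42), 0.06)
  expect_equal(al$n_subjects, 40)
})

test_that("aligned summary signals a cohort without insight", {
  labels <- data.frame(subject = "a", is_insight = FALSE, t_s = NA_real_)
  expect_error(switch_aligned_summary(list(), labels), "no insight")
})

test_that("group contingency table counts and ordering", {
  labels <- data.frame(
    subject = sprintf("s%02d", 1:68),
    is_insight = rep(c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE),
                     c(24, 4, 14, 8, 10, 8)))
  groups <- stats::setNames(rep(c("N2", "N1", "Wake"), c(28, 22, 18)),
                            labels$subject)
  tab <- group_insight_table(labels, groups)
  expect_equal(unclass(tab)[, ],
               matrix(c(24L, 14L, 10L, 4L, 8L, 8L), ncol = 2,
                      dimnames = list(c("N2", "N1", "Wake"),
                                      c("insight", "no_insight"))))
  expect_equal(sum(tab), 68)
  # permutation invariance
  perm <- sample(68)
  expect_equal(group_insight_table(labels[perm, ], groups), tab)
  # error paths
  expect_error(group_insight_table(labels[0, ], groups), "empty")
  bad <- groups; bad[1] <- "REM"
  expect_error(group_insight_table(labels, bad), "unknown group")
})
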