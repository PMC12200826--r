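#' Default nap-study cohort sizes and insight rates
#'
#' Group sizes 28 (N2), 22 (N1), 18 (Wake) with generating insight
#' probabilities 24/28, 14/22 and 10/18 — the study composition whose
#' contingency table the inference layer analyses.
#' @name cohort_defaults
#' @keywords internal
NULL

DEFAULT_N_PER_GROUP <- c(N2 = 28L, N1 = 22L, Wake = 18L)
DEFAULT_INSIGHT_RATES <- c(N2 = 24 / 28, N1 = 14 / 22, Wake = 10 / 18)

# Draw one agent's switch parameters. Switch centres span blocks ~4-6
# (trials 410-620), after the nap boundary; slopes are sharp enough that
# the transition completes within a couple of dozen hard trials.
.draw_agent <- function(is_insight, seed) {
  rng <- local_rng(seed)
  if (is_insight) {
    agent_params(
      is_insight = TRUE,
      t_s_true = sample(410:620, 1L),
      m_true = stats::rlnorm(1, meanlog = log(0.08), sdlog = 0.1)
    )
  } else {
    agent_params(is_insight = FALSE)
  }
}

#' Simulate a full nap-study cohort
#'
#' Generates, per subject: a task schedule and behavioural session from
#' an agent whose insight status is Bernoulli with the group's rate (or
#' fixed by quota), a group-consistent hypnogram, and (optionally) a
#' 20-minute multichannel EEG recording whose stage-wise 1/f exponents
#' may additionally be coupled to insight status.
#'
#' Per-subject random streams are derived from the master seed by a
#' counter scheme, so changing the cohort size does not reshuffle the
#' draws of earlier subjects.
#'
#' @param n_per_group named integer vector (names among Wake/N1/N2).
#' @param insight_rates named numeric vector of generating insight
#'   probabilities per group.
#' @param seed master integer seed.
#' @param quota if TRUE, insight counts per group are fixed to
#'   `round(rate * n)` exactly (and subjects failing the behavioural
#'   inclusion filter are redrawn), so the realised contingency table
#'   equals the generating one — used to reproduce printed tables.
#' @param include_eeg simulate EEG recordings (the expensive part)?
#' @param eeg_params base `eeg_sim_params`; per-subject exponent shifts
#'   are added on top.
#' @param slope_coupling additive increase of the aperiodic exponent for
#'   insight subjects (0 = slopes depend on sleep stage only).
#' @param subject_sd standard deviation of the subject-level exponent
#'   shift.
#' @return list of class `nap_cohort`; each element has `id`, `group`,
#'   `agent`, `session`, `hypnogram`, and `recording` (or NULL).
#' @export
simulate_cohort <- function(n_per_group = DEFAULT_N_PER_GROUP,
                            insight_rates = DEFAULT_INSIGHT_RATES,
                            seed = 1L,
                            quota = FALSE,
                            include_eeg = FALSE,
                            eeg_params = eeg_sim_params(),
                            slope_coupling = 0,
                            subject_sd = 0.1) {
  stopifnot(all(names(n_per_group) %in% c("Wake", "N1", "N2")),
            all(names(n_per_group) %in% names(insight_rates)),
            all(insight_rates[names(n_per_group)] >= 0),
            all(insight_rates[names(n_per_group)] <= 1))
  if (any(n_per_group <= 0)) stop("all group sizes must be positive")
  subjects <- list()
  sid <- 0L
  for (grp in names(n_per_group)) {
    n <- n_per_group[[grp]]
    rate <- insight_rates[[grp]]
    insight_flags <- if (quota) {
      k <- round(rate * n)
      rep(c(TRUE, FALSE), times = c(k, n - k))
    } else {
      rng <- local_rng(derive_seed(seed, match(grp, c("Wake", "N1", "N2"))))
      stats::runif(n) < rate
    }
    for (i in seq_len(n)) {
      sid <- sid + 1L
      attempt <- 0L
      repeat {
        base <- derive_seed(seed, sid * 101L + attempt * 7919L)
        agent <- .draw_agent(insight_flags[i], derive_seed(base, 1L))
        sched <- generate_task_schedule(derive_seed(base, 2L))
        sess <- simulate_agent_responses(sched, agent, derive_seed(base, 3L))
        # quota mode exists to reproduce exact published tables: a
        # subject must pass inclusion AND be classified consistently
        # with its generated insight status, else it is redrawn
        if (!quota) break
        if (.exclusion_reason(sess) == "none") {
          sel <- sess$block == INSTRUCTION_BLOCK - 1L &
            sess$coherence == 0.05
          classified <- mean(sess$correct[sel]) > INSIGHT_ACC_THRESHOLD
          if (classified == insight_flags[i]) break
        }
        attempt <- attempt + 1L
        if (attempt > 50L) stop("quota mode could not draw an includable subject")
      }
      grp_label <- if (grp == "Wake") "Wake" else grp
      hyp <- simulate_hypnogram(grp_label, seed = derive_seed(base, 4L))
      rec <- NULL
      if (include_eeg) {
        rng <- local_rng(derive_seed(base, 5L))
        shift <- stats::rnorm(1, 0, subject_sd) +
          slope_coupling * insight_flags[i]
        pars <- eeg_params
        pars$exponent_shift <- pars$exponent_shift + shift
        rec <- simulate_eeg(hyp, pars, seed = derive_seed(base, 6L))
      }
      subjects[[sid]] <- list(id = sprintf("S%03d", sid), group = grp,
                              agent = agent, session = sess,
                              hypnogram = hyp, recording = rec)
    }
  }
  structure(subjects, class = "nap_cohort")
}

#' @export
print.nap_cohort <- function(x, ...) {
  groups <- vapply(x, `[[`, character(1), "group")
  truth <- vapply(x, function(s) s$agent$is_insight, logical(1))
  cat("Synthetic nap cohort:", length(x), "subjects\n")
  print(table(group = groups, insight_truth = truth))
  invisible(x)
}

#' Ground-truth insight labels of a simulated cohort
#' @param cohort a `nap_cohort`.
#' @return data.frame with `subject`, `group`, `is_insight`, `t_s_true`.
#' @export
cohort_truth <- function(cohort) {
  stopifnot(inherits(cohort, "nap_cohort"))
  data.frame(
    subject = vapply(cohort, `[[`, character(1), "id"),
    group = vapply(cohort, `[[`, character(1), "group"),
    is_insight = vapply(cohort, function(s) s$agent$is_insight, logical(1)),
    t_s_true = vapply(cohort, function(s) s$agent$t_s_true, numeric(1)),
    stringsAsFactors = FALSE
  )
}
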