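#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by point-probability summation: the sum of
#' hypergeometric probabilities of all tables with the observed margins
#' that are no more probable than the observed one (the convention of R's
#' exact test, required to reproduce printed contingency-table p-values).
#' The sample odds ratio (ad/bc) is reported alongside.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return list: `p`, `odds_ratio` (sample OR), `zero_margin` flag.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0),
            all(table == round(table)))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    warning("degenerate table with a zero margin; p = 1 by convention")
    return(list(p = 1, odds_ratio = NA_real_, zero_margin = TRUE))
  }
  p <- stats::fisher.test(table, alternative = "two.sided")$p.value
  or <- (table[1, 1] * table[2, 2]) / (table[1, 2] * table[2, 1])
  list(p = p, odds_ratio = or, zero_margin = FALSE)
}

#' Fit a logistic regression for insight
#'
#' Maximum-likelihood logistic fit (IRLS via `stats::glm`), with sleep
#' stage treatment-coded against the Wake reference level. Reports
#' coefficients with Wald tests, log-likelihood, AIC, and the McFadden
#' R2 adjusted for parameter count (relative to the intercept-only fit
#' on the same subjects).
#'
#' @param formula model formula, e.g. `insight ~ stage + slope`.
#' @param data data.frame with the outcome and predictors; a `stage`
#'   column is releveled to reference "Wake" when present.
#' @return list of class `insight_glm`: `coefficients` (data.frame with
#'   estimate, se, z, p), `logLik`, `AIC`, `k`, `mcfadden_adj_r2`,
#'   `separation`, `fit` (the glm object), `n`.
#' @export
fit_logistic <- function(formula, data) {
  if ("stage" %in% names(data)) {
    data$stage <- stats::relevel(factor(data$stage,
                                        levels = c("Wake", "N1", "N2")),
                                 ref = "Wake")
    data$stage <- droplevels(data$stage)
  }
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(formula, family = stats::binomial(), data = data),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (any(abs(stats::coef(fit)) > 15, na.rm = TRUE)) separation <- TRUE
  sm <- summary(fit)$coefficients
  ll <- as.numeric(stats::logLik(fit))
  k <- attr(stats::logLik(fit), "df")
  null_fit <- stats::glm(stats::update(formula, . ~ 1),
                         family = stats::binomial(), data = data)
  ll0 <- as.numeric(stats::logLik(null_fit))
  structure(
    list(coefficients = data.frame(term = rownames(sm),
                                   estimate = sm[, 1], se = sm[, 2],
                                   z = sm[, 3], p = sm[, 4],
                                   row.names = NULL),
         logLik = ll, AIC = -2 * ll + 2 * k, k = k,
         mcfadden_adj_r2 = 1 - (ll - k) / ll0,
         separation = separation, fit = fit, n = nrow(data)),
    class = "insight_glm"
  )
}

#' @export
print.insight_glm <- function(x, ...) {
  cat(sprintf("Logistic fit: n=%d, logLik=%.3f, AIC=%.2f, adj McFadden R2=%.3f%s\n",
              x$n, x$logLik, x$AIC, x$mcfadden_adj_r2,
              if (x$separation) " [separation]" else ""))
  print(transform(x$coefficients, estimate = round(estimate, 3),
                  se = round(se, 3), z = round(z, 2), p = round(p, 4)))
  invisible(x)
}

#' Likelihood-ratio test between nested logistic fits
#'
#' @param fit_null,fit_full `insight_glm` objects fit to the same
#'   subjects, null nested in full.
#' @return list of class `lrt_result`: `X2`, `df`, `p`.
#' @export
likelihood_ratio_test <- function(fit_null, fit_full) {
  stopifnot(inherits(fit_null, "insight_glm"),
            inherits(fit_full, "insight_glm"))
  if (fit_null$n != fit_full$n) {
    stop("fits use different numbers of subjects")
  }
  null_terms <- labels(stats::terms(stats::formula(fit_null$fit)))
  full_terms <- labels(stats::terms(stats::formula(fit_full$fit)))
  if (!all(null_terms %in% full_terms) || fit_full$k < fit_null$k) {
    stop("models are not properly nested")
  }
  x2 <- 2 * (fit_full$logLik - fit_null$logLik)
  df <- fit_full$k - fit_null$k
  p <- if (df == 0) 1 else stats::pchisq(x2, df, lower.tail = FALSE)
  structure(list(X2 = x2, df = df, p = p), class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT: X2(%d) = %.3f, p = %.4f\n", x$df, x$X2, x$p))
  invisible(x)
}

#' Adjusted McFadden R-squared
#'
#' 1 - (LL_fit - k_fit) / LL_null: pseudo variance explained penalised
#' for parameter count.
#'
#' @param fit an `insight_glm`.
#' @param null_fit the intercept-only `insight_glm` on the same
#'   subjects.
#' @export
mcfadden_adjusted_r2 <- function(fit, null_fit) {
  stopifnot(inherits(fit, "insight_glm"), inherits(null_fit, "insight_glm"))
  if (fit$n != null_fit$n) stop("fits use different subjects")
  if (null_fit$logLik == 0) stop("null log-likelihood is zero")
  1 - (fit$logLik - fit$k) / null_fit$logLik
}

# Coefficient estimate for a term, NA when the term was dropped
# (e.g. a constant covariate made the design rank-deficient).
.term_or_na <- function(fit, term) {
  est <- fit$coefficients$estimate[fit$coefficients$term == term]
  if (length(est) == 0) NA_real_ else est
}

#' Channel-wise nested logistic model comparison
#'
#' For every channel, fits the three-model ladder — baseline
#' (insight ~ stage), full (insight ~ stage + slope), slope-only
#' (insight ~ slope) — and reports AICs, the likelihood-ratio tests
#' baseline-vs-full and slope-only-vs-full, slope coefficients, and
#' which model attains the minimum AIC. Subjects with a missing slope on
#' a channel are dropped case-wise for that channel (count logged).
#'
#' @param slopes data.frame `subject`, `channel`, `slope` (long format,
#'   e.g. from [slope_per_subject()]).
#' @param stage_labels named character vector (subject -> group).
#' @param insight_labels named logical vector (subject -> insight).
#' @return data.frame, one row per channel: AIC columns, LRT statistics
#'   and p-values, slope betas, `best_model`, `n_used`, `n_dropped`.
#' @export
channelwise_model_comparison <- function(slopes, stage_labels,
                                         insight_labels) {
  channels <- unique(slopes$channel)
  rows <- lapply(channels, function(ch) {
    d <- slopes[slopes$channel == ch, ]
    d <- data.frame(subject = d$subject, slope = d$slope,
                    stage = stage_labels[d$subject],
                    insight = insight_labels[d$subject],
                    stringsAsFactors = FALSE)
    n_all <- nrow(d)
    d <- d[stats::complete.cases(d), ]
    base <- fit_logistic(insight ~ stage, d)
    full <- fit_logistic(insight ~ stage + slope, d)
    slope_only <- fit_logistic(insight ~ slope, d)
    lrt_full <- likelihood_ratio_test(base, full)
    lrt_slope <- likelihood_ratio_test(slope_only, full)
    aics <- c(baseline = base$AIC, full = full$AIC,
              slope_only = slope_only$AIC)
    data.frame(
      channel = ch,
      aic_baseline = base$AIC, aic_full = full$AIC,
      aic_slope_only = slope_only$AIC,
      lrt_full_vs_baseline_X2 = lrt_full$X2,
      lrt_full_vs_baseline_p = lrt_full$p,
      lrt_full_vs_slope_X2 = lrt_slope$X2,
      lrt_full_vs_slope_p = lrt_slope$p,
      beta_slope_full = .term_or_na(full, "slope"),
      beta_slope_only = .term_or_na(slope_only, "slope"),
      r2_full = full$mcfadden_adj_r2,
      r2_slope_only = slope_only$mcfadden_adj_r2,
      best_model = names(aics)[which.min(aics)],
      n_used = nrow(d), n_dropped = n_all - nrow(d),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Descriptive two-sample tests
#'
#' Standard two-sided Welch t or two-sample Kolmogorov-Smirnov test.
#'
#' @param x,y numeric samples (>= 2 observations each).
#' @param kind "welch_t" or "ks_2sample".
#' @return list: `statistic`, `df` (Welch only), `p`.
#' @export
descriptive_tests <- function(x, y, kind = c("welch_t", "ks_2sample")) {
  kind <- match.arg(kind)
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (kind == "welch_t") {
    if (stats::var(x) == 0 && stats::var(y) == 0) {
      if (isTRUE(all.equal(mean(x), mean(y)))) {
        return(list(statistic = 0, df = length(x) + length(y) - 2, p = 1))
      }
      stop("degenerate (zero-variance) samples")
    }
    tt <- stats::t.test(x, y)
    list(statistic = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value)
  } else {
    ks <- suppressWarnings(stats::ks.test(x, y))
    list(statistic = unname(ks$statistic), df = NA_real_, p = ks$p.value)
  }
}
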