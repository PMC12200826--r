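test_that("Fisher test matches hand-computed conventions", {
  expect_equal(fisher_exact_2x2(rbind(c(5, 5), c(5, 5)))$p, 1)
  sym <- fisher_exact_2x2(rbind(c(8, 2), c(3, 7)))
  # invariance under transposition and simultaneous row/column swaps
  expect_equal(fisher_exact_2x2(t(rbind(c(8, 2), c(3, 7))))$p, sym$p)
  expect_equal(fisher_exact_2x2(rbind(c(7, 3), c(2, 8)))$p, sym$p)
  expect_equal(sym$odds_ratio, (8 * 7) / (2 * 3))
  expect_warning(z <- fisher_exact_2x2(rbind(c(0, 0), c(3, 7))),
                 "zero margin")
  expect_equal(z$p, 1)
  expect_true(z$zero_margin)
})

test_that("logistic fits reproduce closed forms of the saturated model", {
  counts <- insight_study_counts()
  d <- napinsight:::counts_to_outcomes(counts)
  m1 <- fit_logistic(insight ~ stage, d)
  # saturated single-factor model: fitted cell probabilities equal
  # observed proportions
  probs <- unique(round(stats::fitted(m1$fit), 8))
  expect_setequal(probs, round(c(24 / 28, 14 / 22, 10 / 18), 8))
  # treatment coding against Wake: betas are log odds ratios
  cf <- m1$coefficients
  expect_equal(cf$estimate[cf$term == "stageN2"],
               log((24 / 4) / (10 / 8)), tolerance = 1e-6)
  expect_equal(cf$estimate[cf$term == "stageN1"],
               log((14 / 8) / (10 / 8)), tolerance = 1e-6)
  # Wald SE of the N2 contrast from the classic 1/n sum
  expect_equal(cf$se[cf$term == "stageN2"],
               sqrt(1 / 24 + 1 / 4 + 1 / 10 + 1 / 8), tolerance = 1e-4)
  # AIC identity
  expect_equal(m1$AIC, -2 * m1$logLik + 2 * m1$k, tolerance = 1e-12)
})

test_that("complete separation is flagged", {
  d <- data.frame(insight = rep(c(TRUE, FALSE), each = 10),
                  slope = c(rnorm(10, -2), rnorm(10, 2)))
  m <- fit_logistic(insight ~ slope, d)
  expect_true(m$separation)
})

test_that("likelihood-ratio test ties out against the AIC identity", {
  d <- napinsight:::counts_to_outcomes(insight_study_counts())
  m0 <- fit_logistic(insight ~ 1, d)
  m1 <- fit_logistic(insight ~ stage, d)
  lrt <- likelihood_ratio_test(m0, m1)
  expect_equal(lrt$df, 2)
  expect_equal(lrt$X2, m0$AIC - m1$AIC + 2 * lrt$df, tolerance = 1e-10)
  expect_error(likelihood_ratio_test(m1, m0), "nested")
  # identical models: zero deviance difference, p = 1
  same <- likelihood_ratio_test(m0, m0)
  expect_equal(same$X2, 0)
  expect_equal(same$p, 1)
})

test_that("LRT p-values are uniform under the null", {
  set.seed(5)
  n <- 60
  ps <- vapply(1:300, function(i) {
    d <- data.frame(insight = stats::runif(n) < 0.6, noise = stats::rnorm(n))
    likelihood_ratio_test(fit_logistic(insight ~ 1, d),
                          fit_logistic(insight ~ noise, d))$p
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("adjusted McFadden R2 follows its definition", {
  d <- napinsight:::counts_to_outcomes(insight_study_counts())
  m0 <- fit_logistic(insight ~ 1, d)
  m1 <- fit_logistic(insight ~ stage, d)
  expect_equal(mcfadden_adjusted_r2(m1, m0),
               1 - (m1$logLik - m1$k) / m0$logLik, tolerance = 1e-12)
  # closed-form oracle from the group proportions
  ll1 <- 24 * log(24 / 28) + 4 * log(4 / 28) + 14 * log(14 / 22) +
    8 * log(8 / 22) + 10 * log(10 / 18) + 8 * log(8 / 18)
  ll0 <- 48 * log(48 / 68) + 20 * log(20 / 68)
  expect_equal(mcfadden_adjusted_r2(m1, m0), 1 - (ll1 - 3) / ll0,
               tolerance = 1e-8)
  # null against itself: the algebraic identity 1 - (LL0 - 1)/LL0
  expect_equal(mcfadden_adjusted_r2(m0, m0), 1 - (ll0 - 1) / ll0,
               tolerance = 1e-8)
})

test_that("channel-wise ladder identifies the generating model", {
  set.seed(8)
  n <- 90
  mk_slopes <- function(slope_effect, stage_effect) {
    stage <- sample(c("Wake", "N1", "N2"), n, replace = TRUE)
    base <- c(Wake = -1.37, N1 = -1.47, N2 = -1.79)
    slope <- base[stage] * stage_effect + rnorm(n, 0, 0.15)
    eta <- 0.5 + slope_effect * (-2.5) * (slope - mean(slope)) +
      stage_effect * c(Wake = 0, N1 = 0.3, N2 = 1.4)[stage]
    insight <- runif(n) < plogis(eta)
    list(slopes = do.call(rbind, lapply(c("F4", "C4"), function(ch)
      data.frame(subject = sprintf("s%02d", 1:n), channel = ch,
                 slope = slope + rnorm(n, 0, 0.02)))),
         stage = stats::setNames(stage, sprintf("s%02d", 1:n)),
         insight = stats::setNames(insight, sprintf("s%02d", 1:n)))
  }
  # insight driven by slope only (stage independent given slope)
  d1 <- mk_slopes(slope_effect = 1, stage_effect = 0)
  lad1 <- channelwise_model_comparison(d1$slopes, d1$stage, d1$insight)
  expect_true(mean(lad1$best_model == "slope_only") >= 0.5)
  # insight driven by stage only, slope pure noise
  d2 <- mk_slopes(slope_effect = 0, stage_effect = 1)
  lad2 <- channelwise_model_comparison(d2$slopes, d2$stage, d2$insight)
  expect_true(all(lad2$best_model == "baseline"))
  # missing slopes are dropped case-wise and counted
  d1$slopes$slope[1] <- NA
  lad3 <- channelwise_model_comparison(d1$slopes, d1$stage, d1$insight)
  expect_equal(lad3$n_dropped[lad3$channel == "F4"], 1)
})

test_that("a constant covariate adds nothing to the baseline model", {
  d <- napinsight:::counts_to_outcomes(insight_study_counts())
  d$subject <- sprintf("s%02d", seq_len(nrow(d)))
  slopes <- data.frame(subject = d$subject, channel = "F4", slope = -1.5)
  lad <- suppressWarnings(channelwise_model_comparison(
    slopes, stats::setNames(d$stage, d$subject),
    stats::setNames(d$insight, d$subject)))
  expect_lt(lad$lrt_full_vs_baseline_X2, 1e-6)
})

test_that("descriptive tests handle identity and degenerate cases", {
  expect_equal(descriptive_tests(c(1, 2, 3), c(1, 2, 3), "welch_t")$statistic, 0)
  ks <- descriptive_tests(c(1, 2, 3, 4), c(1, 2, 3, 4), "ks_2sample")
  expect_equal(ks$statistic, 0)
  expect_equal(ks$p, 1)
  expect_error(descriptive_tests(c(1, 1), c(2, 2), "welch_t"), "degenerate")
  # power sanity: a 2-sigma shift is almost always detected
  set.seed(2)
  rej <- vapply(1:200, function(i) {
    descriptive_tests(rnorm(30), rnorm(30, 2), "welch_t")$p < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.9)
})
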