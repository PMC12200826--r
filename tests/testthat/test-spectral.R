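test_that("epoching follows the stride formula", {
  mont <- default_montage()[1, , drop = FALSE]
  rec <- recording(matrix(rnorm(1200 * 200), nrow = 1), 200, mont$channel)
  eps <- epoch_signal(rec)
  expect_equal(dim(eps$data)[1], 399L) # floor((1200-6)/3)+1
  short <- recording(matrix(rnorm(6 * 200), nrow = 1), 200, mont$channel)
  expect_equal(dim(epoch_signal(short)$data)[1], 1L)
  expect_error(epoch_signal(rec, overlap = 1), "overlap")
  tiny <- recording(matrix(rnorm(200), nrow = 1), 200, mont$channel)
  expect_error(epoch_signal(tiny), "shorter")
})

test_that("stage-masked epoching uses only fully-contained windows", {
  mont <- default_montage()[1, , drop = FALSE]
  # 40 epochs: one contiguous block of 10 N2 epochs (300 s)
  labels <- rep("W", 40); labels[11:20] <- "N2"
  hyp <- hypnogram(labels)
  rec <- recording(matrix(rnorm(1200 * 200), nrow = 1), 200, mont$channel)
  eps <- epoch_signal(rec, hyp = hyp, stage = "N2")
  expect_equal(dim(eps$data)[1], 99L) # floor((300-6)/3)+1
  expect_equal(eps$provenance, "deepest-stage")
  # two separated runs of 5 epochs each: stride restarts per run
  labels2 <- rep("W", 40); labels2[c(5:9, 25:29)] <- "N2"
  eps2 <- epoch_signal(rec, hyp = hypnogram(labels2), stage = "N2")
  expect_equal(dim(eps2$data)[1], 2L * (floor((150 - 6) / 3) + 1L))
  # no epochs of a stage never reached
  expect_equal(dim(epoch_signal(rec, hyp = hyp, stage = "N3")$data)[1], 0L)
})

test_that("PSD localises tones and scales with power", {
  fs <- 200
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 10 * t)
  rec <- recording(matrix(x, nrow = 1), fs, "F4")
  spec <- compute_psd(epoch_signal(rec))
  expect_equal(spec$frequencies[which.max(spec$power[1, ])], 10)
  rec2 <- recording(matrix(2 * x, nrow = 1), fs, "F4")
  spec2 <- compute_psd(epoch_signal(rec2))
  expect_equal(spec2$power[1, ], 4 * spec$power[1, ], tolerance = 1e-10)
  expect_error(compute_psd(epoch_signal(recording(
    matrix(rnorm(80 * 60), nrow = 1), 80, "F4"))), "Nyquist")
})

test_that("noiseless model input is recovered to machine-level accuracy", {
  ms <- model_spectrum(b = 1.0, x = 1.5)
  fit <- fit_spectral_model(ms$frequencies, ms$power)
  expect_lt(abs(fit$offset - 1.0), 1e-3)
  expect_lt(abs(fit$exponent - 1.5), 1e-3)
  expect_equal(nrow(fit$peaks), 0)
  # peak-free log-log regression equals the aperiodic fit
  lm_slope <- -coef(lm(log10(ms$power) ~ log10(ms$frequencies)))[[2]]
  expect_lt(abs(fit$exponent - lm_slope), 1e-6)
})

test_that("composite spectra recover both the peak and the exponent", {
  ms <- model_spectrum(b = 1.0, x = 1.5,
                       peaks = data.frame(centre = 10, height = 0.6,
                                          sd = 1.5))
  fit <- fit_spectral_model(ms$frequencies, ms$power)
  expect_equal(nrow(fit$peaks), 1)
  expect_lt(abs(fit$peaks$centre - 10), 0.5)
  expect_lt(abs(fit$exponent - 1.5), 0.05)
  expect_lt(abs(fit$peaks$height - 0.6), 0.1)
})

test_that("fit is scale-equivariant and respects peak constraints", {
  ms <- model_spectrum(b = 1.0, x = 1.2,
                       peaks = data.frame(centre = c(6, 11, 14),
                                          height = c(0.5, 0.7, 0.4),
                                          sd = c(1, 1.2, 0.8)))
  fit <- fit_spectral_model(ms$frequencies, ms$power)
  expect_lte(nrow(fit$peaks), 3)
  expect_true(all(fit$peaks$width >= 0.5 - 1e-9 &
                    fit$peaks$width <= 12 + 1e-9))
  fit10 <- fit_spectral_model(ms$frequencies, ms$power * 10)
  expect_lt(abs(fit10$offset - fit$offset - 1), 1e-6)
  expect_lt(abs(fit10$exponent - fit$exponent), 1e-6)
  expect_error(fit_spectral_model(ms$frequencies, ms$power - 10),
               "strictly positive")
})

test_that("flattened spectra isolate the oscillatory residual", {
  ap <- model_spectrum(b = 1.0, x = 1.5)
  fit <- fit_spectral_model(ap$frequencies, ap$power)
  flat <- flatten_spectrum(ap$frequencies, ap$power, fit)
  expect_lt(max(abs(flat$residual)), 0.01)
  expect_lte(max(flat$frequency), 20)
  comp <- model_spectrum(b = 1.0, x = 1.5,
                         peaks = data.frame(centre = 10, height = 0.6,
                                            sd = 1.5))
  cfit <- fit_spectral_model(comp$frequencies, comp$power)
  cflat <- flatten_spectrum(comp$frequencies, comp$power, cfit)
  expect_equal(cflat$frequency[which.max(cflat$residual)], 10,
               tolerance = 0.05)
  # multiplying power by a constant is absorbed into the offset
  cfit2 <- fit_spectral_model(comp$frequencies, comp$power * 3)
  cflat2 <- flatten_spectrum(comp$frequencies, comp$power * 3, cfit2)
  expect_equal(cflat$residual, cflat2$residual, tolerance = 1e-6)
})

test_that("band power averages the flattened residual inclusively", {
  flat <- data.frame(frequency = seq(1, 20, 0.2),
                     residual = 0)
  for (b in names(oscillatory_bands())) {
    expect_equal(band_power(flat, b), 0)
  }
  flat$residual <- 0.6 * exp(-(flat$frequency - 10)^2 / (2 * 1.5^2))
  expect_gt(band_power(flat, "alpha_cluster"),
            band_power(flat, "spindle_cluster"))
  # single-bin band
  expect_equal(band_power(flat, c(10, 10)),
               flat$residual[flat$frequency == 10])
  expect_error(band_power(flat, c(30, 31)), "no frequency bins")
})

test_that("slope table honours provenance and preserves ordering", {
  mont <- default_montage()[1:2, ]
  nopk <- data.frame(centre = numeric(0), height = numeric(0),
                     width = numeric(0))
  mk <- function(x, group, hyp, seed) {
    par <- eeg_sim_params(montage = mont, stages = list(
      W = list(offset = 1, exponent = x, peaks = nopk),
      N1 = list(offset = 1, exponent = x + 0.1, peaks = nopk),
      N2 = list(offset = 1, exponent = x + 0.4, peaks = nopk)))
    list(id = paste0("s", seed), group = group, hypnogram = hyp,
         recording = simulate_eeg(hyp, par, seed = seed))
  }
  wake_hyp <- hypnogram(rep("W", 20))
  flat <- mk(1.2, "Wake", wake_hyp, 1)
  steep <- mk(1.7, "Wake", wake_hyp, 2)
  cohort <- structure(list(flat, steep), class = "nap_cohort")
  tab <- slope_per_subject(cohort)
  expect_equal(nrow(tab), 4)
  for (ch in mont$channel) {
    expect_lt(tab$slope[tab$subject == "s2" & tab$channel == ch],
              tab$slope[tab$subject == "s1" & tab$channel == ch])
  }
  # whole-nap and deepest-stage coincide for a pure-wake nap
  tab2 <- slope_per_subject(cohort, provenance = "deepest-stage")
  expect_equal(tab$slope, tab2$slope, tolerance = 1e-10)
})
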