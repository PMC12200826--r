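#' Scoring montage with schematic 2-D positions
#'
#' The eight EEG channels used for sleep scoring, with approximate
#' flattened 10-20 coordinates (x towards the right ear, y towards the
#' nasion, unit head radius). Positions feed the spatial adjacency used
#' by the cluster tests.
#' @return data.frame with columns `channel`, `x`, `y`.
#' @export
default_montage <- function() {
  data.frame(
    channel = c("F3", "F4", "C3", "C4", "Cz", "Pz", "O1", "O2"),
    x = c(-0.40, 0.40, -0.55, 0.55, 0.00, 0.00, -0.30, 0.30),
    y = c(0.55, 0.55, 0.00, 0.00, 0.00, -0.50, -0.85, -0.85),
    stringsAsFactors = FALSE
  )
}

#' Stage-specific EEG simulation parameters
#'
#' Defaults encode the canonical deepening of the aperiodic spectrum with
#' sleep depth (exponent x of power ~ 10^b / f^x increasing from wake to
#' N2; reported slopes are -x) together with stage-typical oscillatory
#' peaks: waking alpha, attenuated alpha plus theta in N1, sleep spindles
#' and slow activity in N2/N3. The wake/N1/N2 exponents default to the
#' magnitudes of typical frontal group means (1.37 / 1.47 / 1.79).
#' Peak heights are in log10-power units above the aperiodic component;
#' widths are Gaussian standard deviations in Hz.
#'
#' @param sampling_rate sampling rate in Hz.
#' @param montage channel table from [default_montage()].
#' @param stages named list: per stage, `list(offset=, exponent=,
#'   peaks=data.frame(centre, height, width))`.
#' @param exponent_shift additive shift applied to every stage exponent
#'   (used to couple a subject's aperiodic activity to traits such as
#'   insight propensity).
#' @param highpass_hz cutoff of the Butterworth-like attenuation applied
#'   below 1 Hz, emulating recording high-pass preprocessing.
#' @return list of class `eeg_sim_params`.
#' @export
eeg_sim_params <- function(sampling_rate = 200,
                           montage = default_montage(),
                           stages = list(
                             W = list(offset = 1.10, exponent = 1.37,
                                      peaks = data.frame(centre = 10.0,
                                                         height = 0.60,
                                                         width = 1.5)),
                             N1 = list(offset = 1.25, exponent = 1.47,
                                       peaks = data.frame(
                                         centre = c(9.5, 5.5),
                                         height = c(0.35, 0.15),
                                         width = c(1.8, 2.0))),
                             N2 = list(offset = 1.55, exponent = 1.79,
                                       peaks = data.frame(
                                         centre = c(13.5, 1.5),
                                         height = c(0.55, 0.30),
                                         width = c(1.0, 1.0))),
                             N3 = list(offset = 1.80, exponent = 2.20,
                                       peaks = data.frame(
                                         centre = c(1.2, 13.0),
                                         height = c(0.60, 0.30),
                                         width = c(1.2, 1.5)))
                           ),
                           exponent_shift = 0,
                           highpass_hz = 0.3) {
  for (st in names(stages)) {
    s <- stages[[st]]
    stopifnot(s$exponent + exponent_shift >= 0)
    if (!is.null(s$peaks) && nrow(s$peaks) > 0 &&
        any(s$peaks$centre >= sampling_rate / 2)) {
      stop("peak centre at or above Nyquist for sampling rate ",
           sampling_rate, " Hz")
    }
  }
  exps <- vapply(stages, function(s) s$exponent, numeric(1))
  ord <- match(names(stages), STAGE_LEVELS)
  if (any(diff(exps[order(ord)]) < 0)) {
    stop("stage exponents must be non-decreasing with sleep depth")
  }
  structure(list(sampling_rate = sampling_rate, montage = montage,
                 stages = stages, exponent_shift = exponent_shift,
                 highpass_hz = highpass_hz),
            class = "eeg_sim_params")
}

#' Target one-sided PSD (µV²/Hz) for a stage at given frequencies
#' @keywords internal
stage_target_psd <- function(stage_params, f, exponent_shift = 0,
                             highpass_hz = 0.3) {
  x <- stage_params$exponent + exponent_shift
  b <- stage_params$offset
  f <- pmax(f, 1e-6)
  logp <- b - x * log10(f)
  pk <- stage_params$peaks
  if (!is.null(pk) && nrow(pk) > 0) {
    for (i in seq_len(nrow(pk))) {
      logp <- logp + pk$height[i] *
        exp(-(f - pk$centre[i])^2 / (2 * pk$width[i]^2))
    }
  }
  # order-4 Butterworth magnitude-squared high-pass
  10^logp / (1 + (highpass_hz / f)^8)
}

#' Construct a multichannel recording container
#' @param samples channels x time numeric matrix (µV).
#' @param sampling_rate Hz.
#' @param channel_names character vector, one per row.
#' @param start_offset seconds.
#' @export
recording <- function(samples, sampling_rate, channel_names,
                      start_offset = 0) {
  stopifnot(is.matrix(samples), nrow(samples) == length(channel_names),
            all(is.finite(samples)))
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 channel_names = channel_names,
                 start_offset = start_offset),
            class = "nap_recording")
}

#' @export
print.nap_recording <- function(x, ...) {
  cat("Recording:", nrow(x$samples), "channels,",
      ncol(x$samples) / x$sampling_rate, "s at", x$sampling_rate, "Hz\n")
  invisible(x)
}

#' Simulate a multichannel nap EEG recording from a hypnogram
#'
#' For each 30-s hypnogram epoch, channels are synthesised as white
#' Gaussian noise shaped in the frequency domain to the stage's target
#' spectrum: aperiodic power density proportional to 10^b / f^x plus
#' Gaussian oscillatory bumps in log10 space. The shaping makes the
#' target spectrum exact in expectation, so spectral estimators can be
#' validated by round-trip recovery. Epoch edges carry a short cosine
#' ramp so concatenation does not introduce steps.
#'
#' @param hyp a `hypnogram`.
#' @param params an `eeg_sim_params` object.
#' @param seed integer seed; output is bit-identical under a fixed seed.
#' @return A `nap_recording` of duration `length(hyp$labels) * 30` s.
#' @export
simulate_eeg <- function(hyp, params = eeg_sim_params(), seed = 1L) {
  stopifnot(inherits(hyp, "hypnogram"), inherits(params, "eeg_sim_params"))
  missing_stages <- setdiff(unique(hyp$labels), names(params$stages))
  if (length(missing_stages)) {
    stop("no simulation parameters for stage(s): ",
         paste(missing_stages, collapse = ", "))
  }
  rng <- local_rng(seed)
  fs <- params$sampling_rate
  n_ep <- length(hyp$labels)
  n <- as.integer(hyp$epoch_length * fs)
  n_ch <- nrow(params$montage)
  # frequency axis of the length-n FFT (two-sided, folded)
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * fs / n
  ramp_len <- as.integer(0.025 * fs)
  ramp <- 0.5 * (1 - cos(pi * seq_len(ramp_len) / (ramp_len + 1)))
  out <- matrix(0, nrow = n_ch, ncol = n_ep * n)
  gains <- lapply(unique(hyp$labels), function(st) {
    p <- stage_target_psd(params$stages[[st]], f,
                          exponent_shift = params$exponent_shift,
                          highpass_hz = params$highpass_hz)
    g <- sqrt(p * fs / 2)
    g[1] <- 0 # no DC
    g
  })
  names(gains) <- unique(hyp$labels)
  for (ep in seq_len(n_ep)) {
    g <- gains[[hyp$labels[ep]]]
    idx <- ((ep - 1L) * n + 1L):(ep * n)
    for (ch in seq_len(n_ch)) {
      w <- stats::rnorm(n)
      x <- Re(stats::fft(stats::fft(w) * g, inverse = TRUE)) / n
      x[seq_len(ramp_len)] <- x[seq_len(ramp_len)] * ramp
      x[(n - ramp_len + 1L):n] <- x[(n - ramp_len + 1L):n] * rev(ramp)
      out[ch, idx] <- x
    }
  }
  recording(out, fs, params$montage$channel)
}
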