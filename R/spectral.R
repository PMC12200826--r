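#' Segment a recording into overlapping analysis epochs
#'
#' Cuts the signal into `epoch_s`-second windows with the given overlap
#' (stride `epoch_s * (1 - overlap)`). With a stage mask, only windows
#' fully contained in contiguous 30-s hypnogram epochs of the target
#' stage are kept, so no window mixes sleep stages; the stride formula
#' applies within each contiguous run.
#'
#' @param rec a `nap_recording`.
#' @param epoch_s epoch length in seconds.
#' @param overlap fractional overlap in [0, 1).
#' @param hyp optional `hypnogram` aligned to the recording.
#' @param stage optional stage code; restricts epochs to that stage.
#' @return list of class `eeg_epochs`: `data` (array
#'   epochs x samples x channels), `sampling_rate`, `channel_names`,
#'   `provenance` ("whole-nap" or "deepest-stage").
#' @export
epoch_signal <- function(rec, epoch_s = 6, overlap = 0.5,
                         hyp = NULL, stage = NULL) {
  stopifnot(inherits(rec, "nap_recording"))
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  fs <- rec$sampling_rate
  n <- as.integer(epoch_s * fs)
  if (ncol(rec$samples) < n) stop("recording shorter than one epoch")
  stride <- as.integer(epoch_s * (1 - overlap) * fs)
  runs <- if (is.null(stage)) {
    list(c(1L, ncol(rec$samples)))
  } else {
    stopifnot(inherits(hyp, "hypnogram"))
    lab <- hyp$labels
    spe <- as.integer(hyp$epoch_length * fs) # samples per 30-s epoch
    r <- rle(lab == stage)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    lapply(keep, function(k) {
      c((starts[k] - 1L) * spe + 1L, ends[k] * spe)
    })
  }
  starts <- unlist(lapply(runs, function(rg) {
    if (rg[2] - rg[1] + 1L < n) return(integer(0))
    seq.int(rg[1], rg[2] - n + 1L, by = stride)
  }))
  if (length(starts) == 0) {
    return(structure(list(data = array(0, c(0, n, nrow(rec$samples))),
                          sampling_rate = fs,
                          channel_names = rec$channel_names,
                          provenance = if (is.null(stage)) "whole-nap"
                                       else "deepest-stage"),
                     class = "eeg_epochs"))
  }
  dat <- array(0, c(length(starts), n, nrow(rec$samples)))
  for (ch in seq_len(nrow(rec$samples))) {
    sig <- rec$samples[ch, ]
    for (e in seq_along(starts)) {
      dat[e, , ch] <- sig[starts[e]:(starts[e] + n - 1L)]
    }
  }
  structure(list(data = dat, sampling_rate = fs,
                 channel_names = rec$channel_names,
                 provenance = if (is.null(stage)) "whole-nap"
                              else "deepest-stage"),
            class = "eeg_epochs")
}

#' Average power spectral density over epochs
#'
#' Per-epoch Hanning-tapered periodograms (window-power normalised,
#' one-sided, µV²/Hz), averaged across epochs. Six-second epochs have a
#' native 1/6-Hz resolution; each epoch is therefore zero-padded so the
#' FFT grid contains exact 0.2-Hz multiples, and the spectrum is
#' returned on the 1-45 Hz grid at 0.2-Hz steps.
#'
#' @param epochs an `eeg_epochs` object.
#' @param fmin,fmax frequency range (Hz).
#' @param df target frequency resolution (Hz).
#' @return list of class `spectrum_set`: `power` (channels x
#'   frequencies), `frequencies`, `n_epochs_averaged`, `provenance`.
#' @export
compute_psd <- function(epochs, fmin = 1, fmax = 45, df = 0.2) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (dim(epochs$data)[1] < 1) stop("need at least one epoch")
  fs <- epochs$sampling_rate
  if (fs < 2 * fmax) stop("sampling rate below Nyquist for fmax")
  n <- dim(epochs$data)[2]
  n_ch <- dim(epochs$data)[3]
  # pad so the FFT grid contains exact multiples of df:
  # nfft must be a multiple of fs/df (e.g. 1000 for 0.2 Hz at 200 Hz)
  base <- as.integer(round(fs / df))
  nfft <- as.integer(base * ceiling(n / base))
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1)) # Hanning
  norm <- fs * sum(w^2)
  freqs_full <- fs * (0:(nfft - 1)) / nfft
  step <- as.integer(round(df / (fs / nfft)))
  sel <- seq.int(as.integer(round(fmin / (fs / nfft))) + 1L,
                 as.integer(round(fmax / (fs / nfft))) + 1L, by = step)
  freqs <- freqs_full[sel]
  power <- matrix(0, nrow = n_ch, ncol = length(sel))
  n_ep <- dim(epochs$data)[1]
  for (ch in seq_len(n_ch)) {
    x <- t(matrix(epochs$data[, , ch], nrow = n_ep)) # samples x epochs
    x <- x * w
    if (nfft > n) x <- rbind(x, matrix(0, nfft - n, ncol(x)))
    spec <- stats::mvfft(x)
    p <- 2 * (Mod(spec[sel, , drop = FALSE])^2) / norm
    power[ch, ] <- rowMeans(p)
  }
  structure(list(power = power, frequencies = freqs,
                 n_epochs_averaged = n_ep,
                 channel_names = epochs$channel_names,
                 provenance = epochs$provenance),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat("Spectrum set:", nrow(x$power), "channels,",
      length(x$frequencies), "bins",
      sprintf("(%.1f-%.1f Hz),", min(x$frequencies), max(x$frequencies)),
      x$n_epochs_averaged, "epochs averaged\n")
  invisible(x)
}

# Aperiodic model in log10-log10 space (knee fixed at 0):
# log10 a(f) = b - x * log10(f)
.aperiodic_log <- function(freqs, b, x) b - x * log10(freqs)

# Robust aperiodic fit: initial log-log least squares, then refit on the
# points whose positive residual is below a low percentile — i.e. on the
# bins at or below the initial fit, which excludes oscillatory peaks.
.robust_ap_fit <- function(freqs, log_power, percentile = 0.025) {
  lf <- log10(freqs)
  fit0 <- stats::lm.fit(cbind(1, lf), log_power)
  resid <- log_power - cbind(1, lf) %*% fit0$coefficients
  flat <- pmax(resid, 0)
  thresh <- stats::quantile(flat, percentile, names = FALSE)
  mask <- flat <= thresh
  fit1 <- stats::lm.fit(cbind(1, lf[mask]), log_power[mask])
  cf <- unname(fit1$coefficients)
  c(b = cf[1], x = -cf[2])
}

# Sum of Gaussians in linear frequency (heights in log10-power units).
.gaussians <- function(freqs, pars) {
  g <- numeric(length(freqs))
  if (length(pars) == 0) return(g)
  for (i in seq_len(length(pars) / 3)) {
    c0 <- pars[3 * i - 2]; h <- pars[3 * i - 1]; sd <- pars[3 * i]
    g <- g + h * exp(-(freqs - c0)^2 / (2 * sd^2))
  }
  g
}

#' Default spectral parameterization settings
#'
#' Mirrors the standard settings of the published spectral
#' parameterization procedure: at most 3 peaks, minimum peak height
#' 0.3 log10-power units (3 dB), peak width limits 0.5-12 Hz (Gaussian
#' sd limits 0.25-6 Hz), relative peak threshold 2 sd of the flattened
#' spectrum, robust-fit residual percentile 2.5%.
#' @export
spectral_fit_settings <- function(max_n_peaks = 3,
                                  min_peak_height = 0.3,
                                  peak_threshold = 2,
                                  peak_width_limits = c(0.5, 12),
                                  ap_percentile = 0.025) {
  list(max_n_peaks = max_n_peaks, min_peak_height = min_peak_height,
       peak_threshold = peak_threshold,
       gauss_sd_limits = peak_width_limits / 2,
       ap_percentile = ap_percentile)
}

#' Decompose one power spectrum into aperiodic and oscillatory parts
#'
#' Implements the two-stage procedure of the spectral parameterization
#' algorithm with the knee fixed at zero: (1) robust aperiodic fit in
#' log10-log10 space (initial fit, refit on the low-residual bins);
#' (2) iterative extraction of up to `max_n_peaks` Gaussian peaks from
#' the flattened spectrum, followed by a joint least-squares refinement;
#' (3) final aperiodic refit on the peak-removed spectrum and final peak
#' refinement on the resulting flattened spectrum.
#'
#' @param freqs frequency grid (Hz), strictly increasing, within 1-45.
#' @param power linear power values (µV²/Hz), strictly positive.
#' @param settings from [spectral_fit_settings()].
#' @return list of class `spectral_fit`: `offset` (b), `knee` (0),
#'   `exponent` (x >= 0), `peaks` (data.frame centre, height, width =
#'   2 x Gaussian sd), `fit_error` (RMSE in log10 space), `converged`.
#' @export
fit_spectral_model <- function(freqs, power,
                               settings = spectral_fit_settings()) {
  stopifnot(length(freqs) == length(power), !is.unsorted(freqs))
  if (any(power <= 0)) stop("power values must be strictly positive")
  log_power <- log10(power)
  ap <- .robust_ap_fit(freqs, log_power, settings$ap_percentile)

  extract_peaks <- function(flat) {
    guesses <- numeric(0)
    work <- flat
    for (i in seq_len(settings$max_n_peaks)) {
      idx <- which.max(work)
      height <- work[idx]
      if (height < max(settings$min_peak_height,
                       settings$peak_threshold * stats::sd(work))) break
      centre <- freqs[idx]
      # width guess from half-height crossings
      half <- height / 2
      li <- idx; while (li > 1 && work[li] > half) li <- li - 1
      ri <- idx; while (ri < length(work) && work[ri] > half) ri <- ri + 1
      fwhm <- max(freqs[ri] - freqs[li], 2 * (freqs[2] - freqs[1]))
      sd0 <- min(max(fwhm / 2.355, settings$gauss_sd_limits[1]),
                 settings$gauss_sd_limits[2])
      guesses <- c(guesses, centre, height, sd0)
      work <- work - .gaussians(freqs, c(centre, height, sd0))
    }
    if (length(guesses) == 0) return(numeric(0))
    np <- length(guesses) / 3
    lo <- rep(c(min(freqs), 0, settings$gauss_sd_limits[1]), np)
    hi <- rep(c(max(freqs), 2 * max(flat, 1),
                settings$gauss_sd_limits[2]), np)
    obj <- function(p) sum((flat - .gaussians(freqs, p))^2)
    opt <- stats::optim(guesses, obj, method = "L-BFGS-B",
                        lower = lo, upper = hi)
    opt$par
  }

  flat1 <- log_power - .aperiodic_log(freqs, ap["b"], ap["x"])
  peaks1 <- extract_peaks(flat1)
  # final aperiodic fit on the peak-removed spectrum
  ap2 <- .robust_ap_fit(freqs, log_power - .gaussians(freqs, peaks1),
                        settings$ap_percentile)
  flat2 <- log_power - .aperiodic_log(freqs, ap2["b"], ap2["x"])
  peaks2 <- extract_peaks(flat2)
  model <- .aperiodic_log(freqs, ap2["b"], ap2["x"]) +
    .gaussians(freqs, peaks2)
  rmse <- sqrt(mean((log_power - model)^2))
  np <- length(peaks2) / 3
  peaks_df <- if (np > 0) {
    data.frame(centre = peaks2[3 * seq_len(np) - 2],
               height = peaks2[3 * seq_len(np) - 1],
               width = 2 * peaks2[3 * seq_len(np)])
  } else {
    data.frame(centre = numeric(0), height = numeric(0),
               width = numeric(0))
  }
  structure(
    list(offset = unname(ap2["b"]), knee = 0,
         exponent = max(unname(ap2["x"]), 0),
         peaks = peaks_df, fit_error = rmse, converged = TRUE),
    class = "spectral_fit"
  )
}

#' @export
print.spectral_fit <- function(x, ...) {
  cat(sprintf("Spectral fit: offset %.3f, exponent %.3f (slope %.3f), %d peak(s), RMSE %.4f\n",
              x$offset, x$exponent, -x$exponent, nrow(x$peaks), x$fit_error))
  if (nrow(x$peaks) > 0) print(round(x$peaks, 2))
  invisible(x)
}

#' Flatten a spectrum: periodic residual over a frequency range
#'
#' log10 power minus the fitted aperiodic component, restricted to the
#' oscillatory analysis range (1-20 Hz by default).
#'
#' @param freqs frequency grid of the spectrum.
#' @param power linear power values.
#' @param fit a `spectral_fit` for this spectrum.
#' @param fmax upper frequency bound of the returned residual.
#' @return data.frame `frequency`, `residual`.
#' @export
flatten_spectrum <- function(freqs, power, fit, fmax = 20) {
  stopifnot(inherits(fit, "spectral_fit"))
  sel <- freqs <= fmax + 1e-9
  data.frame(
    frequency = freqs[sel],
    residual = log10(power[sel]) -
      .aperiodic_log(freqs[sel], fit$offset, fit$exponent)
  )
}

#' Frequency bands of the oscillatory analysis
#' @export
oscillatory_bands <- function() {
  list(delta = c(1, 4), alpha_cluster = c(5.8, 11.3),
       spindle_cluster = c(11.5, 15.2))
}

#' Mean flattened power within a frequency band
#'
#' @param flattened data.frame from [flatten_spectrum()].
#' @param band numeric length-2 (Hz, inclusive bounds) or the name of a
#'   band from [oscillatory_bands()].
#' @export
band_power <- function(flattened, band) {
  if (is.character(band)) band <- oscillatory_bands()[[band]]
  stopifnot(length(band) == 2)
  sel <- flattened$frequency >= band[1] - 1e-9 &
    flattened$frequency <= band[2] + 1e-9
  if (!any(sel)) stop("band contains no frequency bins")
  mean(flattened$residual[sel])
}

#' Aperiodic slope per subject and channel
#'
#' Computes, for every cohort subject with a recording, the fitted
#' spectral slope (-x) per channel, using either the whole nap or only
#' the epochs of the subject's deepest sleep stage.
#'
#' @param cohort a `nap_cohort` with recordings.
#' @param provenance "whole-nap" or "deepest-stage".
#' @param settings spectral fit settings.
#' @return data.frame `subject`, `group`, `channel`, `slope`, `offset`,
#'   `n_epochs`, `provenance`; subjects without usable epochs get NA
#'   slopes.
#' @export
slope_per_subject <- function(cohort, provenance = c("whole-nap",
                                                     "deepest-stage"),
                              settings = spectral_fit_settings()) {
  provenance <- match.arg(provenance)
  rows <- list()
  for (s in cohort) {
    if (is.null(s$recording)) next
    eps <- if (provenance == "whole-nap") {
      epoch_signal(s$recording)
    } else {
      epoch_signal(s$recording, hyp = s$hypnogram,
                   stage = deepest_stage(s$hypnogram))
    }
    if (dim(eps$data)[1] < 1) {
      rows[[length(rows) + 1L]] <- data.frame(
        subject = s$id, group = s$group,
        channel = s$recording$channel_names,
        slope = NA_real_, offset = NA_real_, n_epochs = 0L,
        provenance = provenance, stringsAsFactors = FALSE)
      next
    }
    spec <- compute_psd(eps)
    for (ch in seq_along(spec$channel_names)) {
      fit <- fit_spectral_model(spec$frequencies, spec$power[ch, ],
                                settings)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = s$id, group = s$group,
        channel = spec$channel_names[ch],
        slope = -fit$exponent, offset = fit$offset,
        n_epochs = spec$n_epochs_averaged,
        provenance = provenance, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
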