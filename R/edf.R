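# Minimal EDF (European Data Format) support: 16-bit continuous
# recordings, one data record per second, physical units µV. Covers what
# the simulator needs to exchange recordings with standard EEG tooling;
# no annotations, no EDF+.

.edf_field <- function(x, width) {
  s <- substr(as.character(x), 1, width)
  formatC(s, width = width, flag = "-")
}

#' Write a recording to an EDF file
#'
#' 16-bit EDF with one-second data records; the physical range is set
#' symmetrically to the absolute signal maximum, so quantization error
#' is bounded by range / 2^16.
#'
#' @param rec a `nap_recording`.
#' @param path output path.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "nap_recording"))
  fs <- rec$sampling_rate
  stopifnot(fs == round(fs))
  n_ch <- nrow(rec$samples)
  n_rec <- floor(ncol(rec$samples) / fs)
  # physical range quoted at 2 d.p. in the header; round up so no
  # sample exceeds the written range
  phys_max <- ceiling(max(max(abs(rec$samples)), 1e-6) * 100) / 100
  dig_max <- 32767L; dig_min <- -32768L
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edf_field("0", 8),
    .edf_field("synthetic subject", 80),
    .edf_field("synthetic nap recording", 80),
    .edf_field("01.01.00", 8), .edf_field("13.00.00", 8),
    .edf_field(256 * (1 + n_ch), 8),
    .edf_field("", 44),
    .edf_field(n_rec, 8),
    .edf_field("1", 8),
    .edf_field(n_ch, 4)
  )
  sig_hdr <- paste0(
    paste(vapply(rec$channel_names, .edf_field, "", width = 16),
          collapse = ""),
    paste(rep(.edf_field("", 80), n_ch), collapse = ""),
    paste(rep(.edf_field("uV", 8), n_ch), collapse = ""),
    paste(rep(.edf_field(sprintf("%.2f", -phys_max), 8), n_ch),
          collapse = ""),
    paste(rep(.edf_field(sprintf("%.2f", phys_max), 8), n_ch),
          collapse = ""),
    paste(rep(.edf_field(dig_min, 8), n_ch), collapse = ""),
    paste(rep(.edf_field(dig_max, 8), n_ch), collapse = ""),
    paste(rep(.edf_field("", 80), n_ch), collapse = ""),
    paste(rep(.edf_field(fs, 8), n_ch), collapse = ""),
    paste(rep(.edf_field("", 32), n_ch), collapse = "")
  )
  writeChar(paste0(hdr, sig_hdr), con, eos = NULL)
  # physical -> digital mapping (EDF headers quote 2 d.p. ranges, so
  # scale from the written header values to keep the round trip exact)
  pmax_w <- as.numeric(sprintf("%.2f", phys_max))
  scale <- (dig_max - dig_min) / (2 * pmax_w)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    block <- t(rec$samples[, idx, drop = FALSE]) # samples x channels
    dig <- round((block + pmax_w) * scale) + dig_min
    dig <- pmin(pmax(dig, dig_min), dig_max)
    writeBin(as.integer(dig), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()] (or any plain 16-bit EDF)
#'
#' @param path EDF file path.
#' @return a `nap_recording`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8) # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  n_ch <- as.integer(rd(4))
  labels <- vapply(seq_len(n_ch), function(i) rd(16), "")
  for (i in seq_len(n_ch)) rd(80) # transducer
  for (i in seq_len(n_ch)) rd(8)  # unit
  pmin_v <- vapply(seq_len(n_ch), function(i) as.numeric(rd(8)), 0)
  pmax_v <- vapply(seq_len(n_ch), function(i) as.numeric(rd(8)), 0)
  dmin_v <- vapply(seq_len(n_ch), function(i) as.numeric(rd(8)), 0)
  dmax_v <- vapply(seq_len(n_ch), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(n_ch)) rd(80) # prefilter
  spr <- vapply(seq_len(n_ch), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(n_ch)) rd(32)
  fs <- spr[1] / rec_dur
  out <- matrix(0, nrow = n_ch, ncol = n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(n_ch)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2,
                     endian = "little", signed = TRUE)
      phys <- pmin_v[ch] + (dig - dmin_v[ch]) *
        (pmax_v[ch] - pmin_v[ch]) / (dmax_v[ch] - dmin_v[ch])
      out[ch, ((r - 1L) * spr[ch] + 1L):(r * spr[ch])] <- phys
    }
  }
  recording(out, fs, labels)
}
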