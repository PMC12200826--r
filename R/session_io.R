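#' Write a behavioural session to CSV
#'
#' Columns: block, trial, coherence, colour, direction, response,
#' correct, rt_ms.
#' @param session a `session_data`.
#' @param path output path.
#' @export
write_session_csv <- function(session, path) {
  utils::write.csv(as.data.frame(session)[, c(
    "block", "trial", "coherence", "colour", "direction", "response",
    "correct", "rt_ms")], path, row.names = FALSE)
  invisible(path)
}

#' Read a behavioural session from CSV
#' @param path CSV path with the schema of [write_session_csv()].
#' @return a `session_data`.
#' @export
read_session_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("block", "trial", "coherence", "colour", "direction",
            "response", "correct", "rt_ms")
  if (!all(need %in% names(d))) {
    stop("missing session columns: ",
         paste(setdiff(need, names(d)), collapse = ", "))
  }
  d$correct <- as.logical(d$correct)
  attr(d, "colour_onset_trial") <- COLOUR_ONSET_TRIAL
  attr(d, "nap_boundary_trial") <- NAP_BOUNDARY_TRIAL
  attr(d, "instruction_block") <- INSTRUCTION_BLOCK
  class(d) <- c("session_data", "data.frame")
  d
}

#' Write insight labels with exclusion bookkeeping to CSV
#'
#' @param labels classification table (from [classify_cohort()]) merged
#'   with the exclusion log; columns subject, group, is_insight, t_s,
#'   excluded, reason.
#' @param path output path.
#' @export
write_insight_labels <- function(labels, path) {
  utils::write.csv(labels, path, row.names = FALSE)
  invisible(path)
}

#' Write a subject x channel slope table plus fit-settings sidecar
#'
#' @param slopes data.frame from [slope_per_subject()].
#' @param path CSV output path; a `.json` sidecar with the fit settings
#'   is written next to it.
#' @param settings the spectral fit settings used.
#' @export
write_slope_table <- function(slopes, path,
                              settings = spectral_fit_settings()) {
  utils::write.csv(slopes, path, row.names = FALSE)
  jsonlite::write_json(settings, sub("\\.csv$", "_settings.json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a run configuration file (YAML)
#'
#' Flat key-value configuration covering cohort sizes, insight rates,
#' seeds and switches of the simulation pipeline. Unknown keys are
#' rejected so typos fail loudly.
#'
#' @param path YAML file path.
#' @return list of class `run_config` with defaults filled in.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  defaults <- list(
    seed = 1L,
    n_wake = 18L, n_n1 = 22L, n_n2 = 28L,
    rate_wake = 10 / 18, rate_n1 = 14 / 22, rate_n2 = 24 / 28,
    quota = FALSE,
    include_eeg = FALSE,
    slope_coupling = 0,
    n_permutations = 1000L,
    alpha = 0.05, cluster_alpha = 0.05,
    outdir = "results"
  )
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, raw)
  if (is.null(cfg$seed)) stop("config must set a seed")
  structure(cfg, class = "run_config")
}
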