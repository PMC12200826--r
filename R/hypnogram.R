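#' AASM stage codes used by the simulator (no REM in a 20-min nap)
#' @keywords internal
STAGE_LEVELS <- c("W", "N1", "N2", "N3")

#' Construct a hypnogram
#' @param labels character vector of stage codes, one per 30-s epoch.
#' @param epoch_length epoch length in seconds (30 under AASM scoring).
#' @export
hypnogram <- function(labels, epoch_length = 30) {
  stopifnot(all(labels %in% c(STAGE_LEVELS, "R")))
  structure(list(labels = as.character(labels),
                 epoch_length = epoch_length),
            class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  cat("Hypnogram:", length(x$labels), "epochs of", x$epoch_length, "s\n")
  print(table(factor(x$labels, levels = STAGE_LEVELS)))
  invisible(x)
}

#' Deepest stage reached in a hypnogram
#'
#' Stage ordering W < N1 < N2 < N3; a nap is assigned to the group of
#' its deepest stage (the scoring convention for nap group membership).
#' @param hyp a `hypnogram`.
#' @return One of "W", "N1", "N2", "N3".
#' @export
deepest_stage <- function(hyp) {
  stopifnot(inherits(hyp, "hypnogram"))
  present <- STAGE_LEVELS %in% hyp$labels
  STAGE_LEVELS[max(which(present))]
}

#' Simulate a 20-minute nap hypnogram for a sleep group
#'
#' Generates 30-s stage labels consistent with group membership as scored
#' in nap studies: the Wake group never leaves W; the N1 group reaches N1
#' (at least one epoch) but never N2; the N2 group reaches N2. Sleep
#' latency and stage-run durations are drawn from geometric
#' distributions, giving the irregular, fragmented stage sequences
#' typical of short daytime naps.
#'
#' @param group one of "Wake", "N1", "N2".
#' @param seed integer seed.
#' @param n_epochs number of 30-s epochs (40 = 20 minutes).
#' @param mean_latency_epochs mean wake epochs before sleep onset.
#' @param mean_n1_run mean length (epochs) of an N1 run.
#' @param min_n2_minutes minimum total N2 duration for N2-group naps;
#'   naps are redrawn internally until the quota is met (mirrors the
#'   exclusion of naps with under two minutes of N2).
#' @return A `hypnogram`.
#' @export
simulate_hypnogram <- function(group = c("Wake", "N1", "N2"), seed = 1L,
                               n_epochs = 40L, mean_latency_epochs = 8,
                               mean_n1_run = 4, min_n2_minutes = 2) {
  group <- match.arg(group)
  rng <- local_rng(seed)
  if (group == "Wake") {
    return(hypnogram(rep("W", n_epochs)))
  }
  min_n2_epochs <- ceiling(min_n2_minutes * 60 / 30)
  repeat {
    labels <- rep("W", n_epochs)
    # sleep onset latency
    lat <- min(stats::rgeom(1, 1 / mean_latency_epochs) + 2L, n_epochs - 4L)
    i <- lat + 1L
    state <- "N1"
    while (i <= n_epochs) {
      run <- stats::rgeom(1, 1 / mean_n1_run) + 1L
      run <- min(run, n_epochs - i + 1L)
      labels[i:(i + run - 1L)] <- state
      i <- i + run
      state <- if (group == "N2") {
        # N2-group naps deepen, with occasional brief arousals
        sample(c("N1", "N2", "W"), 1L, prob = c(0.25, 0.65, 0.10))
      } else {
        sample(c("N1", "W"), 1L, prob = c(0.7, 0.3))
      }
    }
    ok <- switch(group,
      N1 = any(labels == "N1") && !any(labels %in% c("N2", "N3")),
      N2 = sum(labels == "N2") >= min_n2_epochs
    )
    if (ok) {
      return(hypnogram(labels))
    }
  }
}

#' Write a hypnogram as plain text (one stage code per line)
#' @param hyp a `hypnogram`.
#' @param path output file path.
#' @export
write_hypnogram <- function(hyp, path) {
  stopifnot(inherits(hyp, "hypnogram"))
  writeLines(hyp$labels, path)
  invisible(path)
}

#' Read a plain-text hypnogram (one AASM code per line per 30 s)
#' @param path file path.
#' @param epoch_length epoch length in seconds.
#' @export
read_hypnogram <- function(path, epoch_length = 30) {
  hypnogram(trimws(readLines(path)), epoch_length = epoch_length)
}
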