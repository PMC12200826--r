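# Seed management.
#
# Simulators take explicit integer seeds; they seed R's RNG locally and
# restore the caller's RNG state on exit, so library use never clobbers a
# user's random stream. Per-subject streams are derived from a master seed
# by a counter scheme (a multiplicative congruential hash), so growing a
# cohort does not reshuffle the streams of earlier subjects.

#' Seed the RNG for the calling function, restoring state on exit
#' @param seed integer seed
#' @param env caller environment whose exit restores the RNG state
#' @keywords internal
local_rng <- function(seed, env = parent.frame()) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  restore <- if (is.null(old)) {
    quote(if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  } else {
    bquote(assign(".Random.seed", .(old), envir = globalenv()))
  }
  do.call(on.exit, list(restore, add = TRUE), envir = env)
  set.seed(as.integer(seed))
  invisible(seed)
}

#' Derive a child stream seed from a master seed and a counter
#'
#' Deterministic, stays below 2^31 so it is a valid R integer seed.
#' @param master master integer seed
#' @param index non-negative counter (e.g. subject number)
#' @keywords internal
derive_seed <- function(master, index) {
  m <- 2147483647 # 2^31 - 1
  s <- (abs(as.numeric(master)) %% m)
  s <- (s * 48271 + as.numeric(index)) %% m
  s <- (s * 69621 + 12345) %% m
  as.integer(s)
}
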