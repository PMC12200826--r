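#' Coherence levels of the random-dot task
#'
#' The five noise levels used in the main task phase, as fractions of
#' coherently moving dots, plus the 100% training level.
#' @keywords internal
COHERENCE_LEVELS <- c(0.05, 0.23, 0.41, 0.59, 0.76)

#' Trial at which the colour feature becomes predictive (mid block 4).
#' @keywords internal
COLOUR_ONSET_TRIAL <- 351L

#' Last trial before the nap break (end of block 4).
#' @keywords internal
NAP_BOUNDARY_TRIAL <- 400L

#' Block in which the colour rule is explicitly instructed.
#' @keywords internal
INSTRUCTION_BLOCK <- 9L

# Per-100-trial coherence quotas for the full-noise blocks (3-9):
# the hardest level (5%) is over-represented at 30/100; the rest get
# 10 (23%), 20 (41%), 20 (59%), 20 (76%).
.block_quota <- function() {
  rep(COHERENCE_LEVELS, times = c(30L, 10L, 20L, 20L, 20L))
}

#' Generate the 900-trial task schedule
#'
#' Builds the fixed trial schedule of the perceptual strategy-switch task:
#' 9 blocks of 100 trials. Block 1 is pure training at 100% motion
#' coherence; block 2 uses only the three easiest noise levels
#' (41/59/76%); blocks 3-9 use all five levels with 30 trials per 100 at
#' the hardest (5%) level and 10/20/20/20 at the remaining levels.
#' Colour is random and non-predictive for trials 1-350 and becomes
#' deterministically mapped to the correct response diagonal from trial
#' 351 onward. Block 9 is flagged as instructed.
#'
#' @param seed Integer seed controlling the within-block shuffling of
#'   coherence levels, colours and motion directions.
#' @return A data.frame of class `task_schedule` with columns
#'   `block`, `trial`, `coherence`, `colour`, `direction`,
#'   `colour_predictive`, `instructed`, and the correct response in
#'   `correct_key` ("L" for the NW/SE diagonal, "R" for NE/SW).
#' @examples
#' sched <- generate_task_schedule(seed = 1)
#' table(sched$coherence[sched$block == 3])
#' @export
generate_task_schedule <- function(seed = 1L) {
  rng <- local_rng(seed)
  blocks <- vector("list", 9L)
  for (b in 1:9) {
    coh <- if (b == 1L) {
      rep(1.00, 100L)
    } else if (b == 2L) {
      sample(rep(c(0.41, 0.59, 0.76), length.out = 100L))
    } else {
      sample(.block_quota())
    }
    direction <- sample(c("NW", "NE", "SW", "SE"), 100L, replace = TRUE)
    blocks[[b]] <- data.frame(
      block = b, trial = (b - 1L) * 100L + 1:100,
      coherence = coh, direction = direction,
      stringsAsFactors = FALSE
    )
  }
  sched <- do.call(rbind, blocks)
  # NW/SE diagonal -> left key, NE/SW -> right key
  sched$correct_key <- ifelse(sched$direction %in% c("NW", "SE"), "L", "R")
  sched$colour_predictive <- sched$trial >= COLOUR_ONSET_TRIAL
  # Fixed colour mapping: orange predicts the left (NW/SE) diagonal.
  random_colour <- sample(c("orange", "purple"), 900L, replace = TRUE)
  mapped_colour <- ifelse(sched$correct_key == "L", "orange", "purple")
  sched$colour <- ifelse(sched$colour_predictive, mapped_colour, random_colour)
  sched$instructed <- sched$block == INSTRUCTION_BLOCK
  rownames(sched) <- NULL
  class(sched) <- c("task_schedule", "data.frame")
  sched
}

#' @export
print.task_schedule <- function(x, ...) {
  cat("Task schedule:", nrow(x), "trials,",
      length(unique(x$block)), "blocks\n")
  cat("Colour predictive from trial", min(x$trial[x$colour_predictive]), "\n")
  invisible(x)
}
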