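#' Construct behavioural agent parameters
#'
#' An agent follows a motion-based strategy whose accuracy is a monotone
#' function of motion coherence; insight agents switch, via a sigmoid
#' transition centred at `t_s_true` with per-trial slope `m_true`, to a
#' colour-based strategy with accuracy `p_colour` once the colour feature
#' is predictive. The default psychometric curve is calibrated so that
#' pre-switch accuracy is 56% at 5% coherence and 92% at the lowest noise
#' level (76% coherence), with a perfect ceiling at full coherence.
#'
#' @param is_insight logical; does this agent ever switch strategy?
#' @param t_s_true switch centre (trial index); insight agents must
#'   switch within the colour-predictive phase (trials 351-900).
#' @param m_true positive per-trial sigmoid slope of the strategy switch.
#' @param p_motion named numeric vector mapping coherence level to
#'   probability correct under the motion strategy (monotone in
#'   coherence, values in [0.5, 1]).
#' @param p_colour probability correct under the colour strategy,
#'   in (0.5, 1].
#' @param lapse lapse rate in [0, 0.1]: probability mass mixed towards
#'   chance (0.5) on every trial.
#' @param rt_mean_pre,rt_mean_post mean reaction times (ms) before and
#'   after the strategy switch; draws are log-normal.
#' @param rt_sdlog log-scale standard deviation of reaction times.
#' @return A list of class `agent_params`.
#' @export
agent_params <- function(is_insight,
                         t_s_true = NA_real_,
                         m_true = 0.08,
                         p_motion = c("0.05" = 0.56, "0.23" = 0.72,
                                      "0.41" = 0.83, "0.59" = 0.89,
                                      "0.76" = 0.92, "1" = 1.00),
                         p_colour = 0.97,
                         lapse = 0.02,
                         rt_mean_pre = 767, rt_mean_post = 527,
                         rt_sdlog = 0.25) {
  stopifnot(is.logical(is_insight), length(is_insight) == 1L)
  if (is.unsorted(p_motion)) {
    stop("p_motion must be monotone non-decreasing in coherence")
  }
  stopifnot(all(p_motion >= 0.5), all(p_motion <= 1),
            p_colour > 0.5, p_colour <= 1,
            lapse >= 0, lapse <= 0.1, m_true >= 0)
  if (is_insight) {
    if (is.na(t_s_true) || t_s_true < COLOUR_ONSET_TRIAL || t_s_true > 900) {
      stop("invalid agent: insight agents need t_s_true within [351, 900]")
    }
  }
  structure(
    list(is_insight = is_insight, t_s_true = t_s_true, m_true = m_true,
         p_motion = p_motion, p_colour = p_colour, lapse = lapse,
         rt_mean_pre = rt_mean_pre, rt_mean_post = rt_mean_post,
         rt_sdlog = rt_sdlog),
    class = "agent_params"
  )
}

# Motion-strategy probability correct for a vector of coherences.
.p_motion_at <- function(agent, coherence) {
  lev <- as.numeric(names(agent$p_motion))
  idx <- match(coherence, lev)
  if (anyNA(idx)) {
    # interpolate for non-tabulated coherences
    return(stats::approx(lev, agent$p_motion, xout = coherence,
                         rule = 2)$y)
  }
  unname(agent$p_motion[idx])
}

#' Sigmoid weight of the colour strategy at given trials
#' @keywords internal
switch_weight <- function(trial, t_s, m) {
  1 / (1 + exp(-m * (trial - t_s)))
}

#' Simulate one agent's session on a task schedule
#'
#' Correctness per trial is Bernoulli with probability equal to a mixture
#' of the motion-strategy psychometric curve and the colour-strategy
#' accuracy, weighted by the agent's sigmoid switch function (weight 0
#' until the colour feature is predictive, and identically 0 for
#' non-insight agents). In the instructed final block all agents use the
#' colour strategy. Reaction times are log-normal, faster post-switch.
#'
#' @param schedule a `task_schedule`.
#' @param agent an `agent_params` object.
#' @param seed integer seed.
#' @return A data.frame of class `session_data` with columns
#'   `block,trial,coherence,colour,direction,response,correct,rt_ms`.
#'   The phase markers (colour onset 351, nap boundary 400, instruction
#'   block 9) travel as attributes.
#' @export
simulate_agent_responses <- function(schedule, agent, seed = 1L) {
  stopifnot(inherits(schedule, "task_schedule"), inherits(agent, "agent_params"))
  rng <- local_rng(seed)
  n <- nrow(schedule)
  w <- numeric(n)
  if (agent$is_insight) {
    w <- switch_weight(schedule$trial, agent$t_s_true, agent$m_true)
    w[!schedule$colour_predictive] <- 0
  }
  # Explicit instruction: everyone adopts the colour strategy in block 9.
  w[schedule$instructed] <- 1
  p <- (1 - w) * .p_motion_at(agent, schedule$coherence) + w * agent$p_colour
  p <- (1 - agent$lapse) * p + agent$lapse * 0.5
  correct <- stats::runif(n) < p
  other <- c(L = "R", R = "L")
  response <- ifelse(correct, schedule$correct_key,
                     other[schedule$correct_key])
  rt_mean <- (1 - w) * agent$rt_mean_pre + w * agent$rt_mean_post
  mu <- log(rt_mean) - agent$rt_sdlog^2 / 2
  rt <- stats::rlnorm(n, meanlog = mu, sdlog = agent$rt_sdlog)
  out <- data.frame(
    block = schedule$block, trial = schedule$trial,
    coherence = schedule$coherence, colour = schedule$colour,
    direction = schedule$direction, response = unname(response),
    correct = correct, rt_ms = rt, stringsAsFactors = FALSE
  )
  attr(out, "colour_onset_trial") <- COLOUR_ONSET_TRIAL
  attr(out, "nap_boundary_trial") <- NAP_BOUNDARY_TRIAL
  attr(out, "instruction_block") <- INSTRUCTION_BLOCK
  class(out) <- c("session_data", "data.frame")
  out
}
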