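# Adaptive calibration of the contrast differential: simulated psychometric
# observers, the two transformed up-down staircases, a grid-based QUEST
# titration, and the 30-trial verification block.

#' Simulated psychometric observer
#'
#' A stand-in for a human participant, used to exercise the adaptive
#' calibration procedures. Performance on the 2AFC contrast discrimination
#' follows a Weibull psychometric function parameterised directly by the
#' contrast differential at which the observer scores 70% correct:
#' \deqn{P(correct) = \gamma + (1 - \gamma - \lambda)\,
#'   (1 - e^{-(x/\alpha)^\beta})}
#' with guess rate \eqn{\gamma = 0.5} and \eqn{\alpha} solved so that
#' \eqn{P(threshold) = 0.70} exactly. `bias_20hz_pct` models the perceptual
#' "flicker bias" whereby the grating phase-reversing at the higher
#' frequency is perceived at lower contrast: when the two gratings differ
#' only in flicker frequency, the observer prefers the 20 Hz grating unless
#' the 25 Hz grating receives a compensatory contrast boost of this size.
#'
#' @param threshold_pct Contrast differential (target minus non-target
#'   contrast, percentage points) yielding 70% correct.
#' @param slope Weibull slope (dimensionless).
#' @param lapse_rate Lapse probability in \[0, 0.1\].
#' @param bias_20hz_pct Contrast boost (pp) to the 25 Hz grating at which
#'   the observer is indifferent between the two flicker frequencies.
#' @param bias_spread_pct Softness of the flicker preference (logistic
#'   scale parameter, pp).
#' @return A list with class `observer`.
#' @export
observer <- function(threshold_pct = 15, slope = 3.5, lapse_rate = 0.02,
                     bias_20hz_pct = 0, bias_spread_pct = 4) {
  stopifnot(threshold_pct > 0, slope > 0,
            lapse_rate >= 0, lapse_rate <= 0.1)
  structure(
    list(threshold_pct = threshold_pct, slope = slope,
         lapse_rate = lapse_rate, guess_rate = 0.5,
         bias_20hz_pct = bias_20hz_pct, bias_spread_pct = bias_spread_pct),
    class = "observer"
  )
}

# P(correct) of a 2AFC Weibull observer at a contrast differential (pp).
weibull_p_correct <- function(contrast_diff_pct, threshold_pct, slope,
                              lapse_rate, guess_rate = 0.5,
                              target_p = 0.70) {
  k <- -log(1 - (target_p - guess_rate) / (1 - guess_rate - lapse_rate))
  alpha <- threshold_pct / k^(1 / slope)
  guess_rate + (1 - guess_rate - lapse_rate) *
    (1 - exp(-(contrast_diff_pct / alpha)^slope))
}

#' Simulate one observer response
#'
#' Draws a Bernoulli correct/error response from the observer's Weibull
#' psychometric function at the given contrast differential.
#'
#' @param obs An [observer()].
#' @param contrast_diff_pct Contrast differential (pp) in \[0, 100\].
#' @param seed Integer seed (the draw is deterministic given the seed).
#' @return Logical: was the response correct?
#' @export
observer_respond <- function(obs, contrast_diff_pct, seed) {
  stopifnot(contrast_diff_pct >= 0, contrast_diff_pct <= 100)
  local_rng(seed)
  p <- weibull_p_correct(contrast_diff_pct, obs$threshold_pct, obs$slope,
                         obs$lapse_rate)
  stats::runif(1) < p
}

# P(observer chooses the 25 Hz grating) when the gratings differ only in
# flicker frequency and the 25 Hz grating carries a contrast boost (pp).
observer_p_choose_25 <- function(obs, boost_pct) {
  stats::plogis((boost_pct - obs$bias_20hz_pct) / obs$bias_spread_pct)
}

#' Initialise a staircase
#'
#' One-up-two-down staircases converge on the level with
#' \eqn{P(correct) = \sqrt{0.5} \approx 70.7\%}; one-up-one-down staircases
#' converge on the 50% point and are used to estimate the flicker-bias
#' contrast boost. The step size halves at every reversal down to a 1 pp
#' floor. Termination follows the task rules: after four reversals, or after
#' `max_trials` trials (50 for the one-up-two-down estimation staircases, 60
#' for the one-up-one-down validation staircase).
#'
#' @param rule `"one_up_two_down"` or `"one_up_one_down"`.
#' @param start_level_pct Initial level: the estimation staircases start
#'   from 100% differential evidence; the flicker-bias staircase starts
#'   from a zero boost.
#' @param step_pct Initial step size (pp).
#' @param max_reversals,max_trials Termination bounds.
#' @param n_discard_reversals Early reversals excluded from the
#'   converged-level estimate. The one-up-two-down staircases approach
#'   threshold from far above, so their first two reversals are transient
#'   and discarding them removes the approach bias; the one-up-one-down
#'   staircase starts at zero boost near its convergence point and keeps
#'   all reversals.
#' @return A list with class `staircase_state`.
#' @export
staircase <- function(rule = c("one_up_two_down", "one_up_one_down"),
                      start_level_pct = if (match.arg(rule) ==
                        "one_up_two_down") 100 else 0,
                      step_pct = if (match.arg(rule) ==
                        "one_up_two_down") 16 else 8,
                      max_reversals = 4L,
                      max_trials = if (match.arg(rule) == "one_up_two_down")
                        50L else 60L,
                      n_discard_reversals = if (match.arg(rule) ==
                        "one_up_two_down") 2L else 0L) {
  rule <- match.arg(rule)
  structure(
    list(rule = rule, current_level_pct = start_level_pct,
         step_pct = step_pct, step_floor_pct = 1,
         n_discard_reversals = as.integer(n_discard_reversals),
         n_reversals = 0L, trial_count = 0L,
         max_reversals = as.integer(max_reversals),
         max_trials = as.integer(max_trials),
         consec_correct = 0L, last_move = 0L,
         terminated = FALSE, reversal_levels = numeric(0),
         history = data.frame(level = numeric(0), response = logical(0))),
    class = "staircase_state"
  )
}

#' Advance a staircase by one response
#'
#' Applies the transformed up-down rule: under one-up-two-down the level
#' decreases after two consecutive correct responses and increases after any
#' error; under one-up-one-down it decreases after each correct response and
#' increases after each error. A reversal is a change in movement direction;
#' the step halves at each reversal (floor 1 pp) and levels are clipped to
#' \[0, 100\].
#'
#' @param state A `staircase_state`.
#' @param response Logical; correct (or, for the flicker staircase, "chose
#'   the 25 Hz grating").
#' @return The updated `staircase_state`.
#' @export
staircase_step <- function(state, response) {
  if (state$terminated) stop("staircase already terminated")
  state$trial_count <- state$trial_count + 1L
  state$history <- rbind(state$history,
                         data.frame(level = state$current_level_pct,
                                    response = response))

  move <- 0L
  if (state$rule == "one_up_two_down") {
    if (response) {
      state$consec_correct <- state$consec_correct + 1L
      if (state$consec_correct >= 2L) {
        move <- -1L
        state$consec_correct <- 0L
      }
    } else {
      move <- +1L
      state$consec_correct <- 0L
    }
  } else {
    move <- if (response) -1L else +1L
  }

  if (move != 0L) {
    if (state$last_move != 0L && move != state$last_move) {
      state$n_reversals <- state$n_reversals + 1L
      state$reversal_levels <- c(state$reversal_levels,
                                 state$current_level_pct)
      state$step_pct <- max(state$step_pct / 2, state$step_floor_pct)
    }
    state$current_level_pct <- min(100, max(0,
      state$current_level_pct + move * state$step_pct))
    state$last_move <- move
  }

  if (state$n_reversals >= state$max_reversals ||
      state$trial_count >= state$max_trials) {
    state$terminated <- TRUE
  }
  state
}

#' Run a staircase to termination against a simulated observer
#'
#' @param state A `staircase_state`.
#' @param respond Function `(level_pct) -> logical` giving the simulated
#'   response at a level.
#' @return The terminated `staircase_state`; `$converged_level_pct` holds
#'   the mean level at the reversals (or the final level if no reversal
#'   occurred).
#' @export
staircase_run <- function(state, respond) {
  while (!state$terminated) {
    state <- staircase_step(state, respond(state$current_level_pct))
  }
  state$converged_level_pct <- staircase_converged_level(state)
  state
}

staircase_converged_level <- function(state) {
  rl <- state$reversal_levels
  d <- state$n_discard_reversals
  if (length(rl) > d) mean(rl[(d + 1):length(rl)])
  else if (length(rl) > 0) mean(rl)
  else state$current_level_pct
}

#' Estimate the flicker-bias contrast boost
#'
#' Runs the one-up-one-down validation staircase in which the 25 Hz grating
#' is always the correct answer: the staircase adjusts the contrast boost to
#' the 25 Hz grating until the observer chooses it on 50% of trials (the
#' gratings are then perceptually indistinguishable).
#'
#' @param obs An [observer()] (its `bias_20hz_pct` is the ground truth).
#' @param start_boost_pct,step_pct Staircase initialisation.
#' @param seed Integer seed.
#' @return The terminated `staircase_state` (see [staircase_run()]).
#' @export
flicker_bias_staircase <- function(obs, start_boost_pct = 0, step_pct = 8,
                                   seed = 1L) {
  local_rng(seed)
  st <- staircase("one_up_one_down", start_level_pct = start_boost_pct,
                  step_pct = step_pct)
  staircase_run(st, function(level) {
    stats::runif(1) < observer_p_choose_25(obs, level)
  })
}

#' Grid-based QUEST titration of the contrast differential
#'
#' Maintains a posterior over the 70%-correct contrast differential on a
#' log-spaced grid covering 0.5 to 100 pp, assuming a Weibull psychometric
#' model (slope 3.5, guess rate 0.5, lapse 0.02) and a lognormal prior
#' centred at 20 pp. Each trial is placed at the current posterior mean and
#' the posterior is updated with the Bernoulli likelihood of the observed
#' response; the estimate is the posterior mean after `n_trials` trials.
#' If the estimated differential implies a target contrast level above 65%
#' (differential above 30 pp, since the target sits at 50 + differential/2),
#' the insufficient-practice flag is raised.
#'
#' @param obs An [observer()].
#' @param n_trials Number of QUEST trials (default 60).
#' @param seed Integer seed.
#' @param start_level_pct Optional first test level (e.g. the final level of
#'   the practice block); defaults to the prior mean.
#' @param grid_n Grid resolution.
#' @return A list with class `quest_result`: `estimate_pct` (posterior-mean
#'   contrast differential), `sd_pct` (posterior SD, the QUEST margin of
#'   error), `insufficient_practice` flag, `posterior`, `grid_pct`,
#'   `trials` (levels and responses).
#' @export
quest_run <- function(obs, n_trials = 60L, seed = 1L,
                      start_level_pct = NULL, grid_n = 200L) {
  stopifnot(n_trials >= 1L)
  local_rng(seed)

  grid <- exp(seq(log(0.5), log(100), length.out = grid_n))
  prior <- stats::dlnorm(grid, meanlog = log(20), sdlog = 0.6)
  prior <- prior / sum(prior)
  post <- prior

  beta <- 3.5; gamma <- 0.5; lapse <- 0.02
  levels <- numeric(n_trials)
  resp <- logical(n_trials)
  level <- if (is.null(start_level_pct)) sum(post * grid) else start_level_pct

  for (t in seq_len(n_trials)) {
    level <- min(100, max(0.5, level))
    levels[t] <- level
    p_true <- weibull_p_correct(level, obs$threshold_pct, obs$slope,
                                obs$lapse_rate)
    r <- stats::runif(1) < p_true
    resp[t] <- r
    # likelihood of the response under each candidate threshold
    p_model <- weibull_p_correct(level, grid, beta, lapse, gamma)
    post <- post * if (r) p_model else (1 - p_model)
    z <- sum(post)
    if (z <= 0 || !is.finite(z)) {
      stop("degenerate QUEST posterior: all mass lost")
    }
    post <- post / z
    if (post[1] > 0.999 || post[length(post)] > 0.999) {
      stop("degenerate QUEST posterior: mass concentrated at a grid bound")
    }
    level <- sum(post * grid)
  }

  est <- sum(post * grid)
  sdv <- sqrt(sum(post * grid^2) - est^2)
  structure(
    list(estimate_pct = est, sd_pct = sdv,
         insufficient_practice = (50 + est / 2) > 65,
         posterior = post, grid_pct = grid,
         trials = data.frame(level = levels, response = resp)),
    class = "quest_result"
  )
}

#' Verification block for the titrated contrast differential
#'
#' Presents `n_trials` trials at the QUEST-estimated contrast differential
#' and compares accuracy with the 70% goal. The differential is then
#' adjusted by the QUEST margin of error in the direction that moves
#' accuracy toward 70% (no adjustment when accuracy is exactly 70%). If
#' accuracy differs from 70% by 5 percentage points or more, the
#' verification block must be rerun at the adjusted differential.
#'
#' @param obs An [observer()].
#' @param contrast_diff_pct Differential under verification (pp).
#' @param n_trials Verification block length (default 30).
#' @param quest_margin Adjustment magnitude (pp), e.g. the QUEST posterior
#'   SD.
#' @param seed Integer seed.
#' @return A list: `accuracy_pct`, `adjusted_contrast_pct`, `rerun`.
#' @export
verify_titration <- function(obs, contrast_diff_pct, n_trials = 30L,
                             quest_margin = 2, seed = 1L) {
  local_rng(seed)
  p <- weibull_p_correct(contrast_diff_pct, obs$threshold_pct, obs$slope,
                         obs$lapse_rate)
  acc <- 100 * mean(stats::runif(n_trials) < p)
  dir <- sign(70 - acc)   # under 70% -> raise the differential
  adj <- contrast_diff_pct + dir * quest_margin
  list(accuracy_pct = acc,
       adjusted_contrast_pct = min(100, max(0.5, adj)),
       rerun = abs(acc - 70) >= 5)
}

#' Simulate a full calibration phase
#'
#' Chains the calibration stages against one simulated observer: the two
#' interleaved one-up-two-down staircases (both gratings at the same
#' flicker frequency), the one-up-one-down flicker-bias staircase, the
#' 60-trial QUEST titration seeded with the staircase level, and the
#' 30-trial verification block (rerun once if accuracy misses 70% by 5 pp
#' or more).
#'
#' @param obs An [observer()].
#' @param seed Integer seed.
#' @return A list with the stage results and the final
#'   `contrast_diff_pct` to use in the main task.
#' @export
calibrate_session <- function(obs, seed = 1L) {
  # two interleaved one-up-two-down staircases, alternating trial order;
  # differential evidence starts at 100%
  st <- list(staircase("one_up_two_down"),
             staircase("one_up_two_down"))
  k <- 0L
  turn <- 1L
  while (!(st[[1]]$terminated && st[[2]]$terminated)) {
    if (st[[turn]]$terminated) turn <- 3L - turn
    k <- k + 1L
    r <- observer_respond(obs, st[[turn]]$current_level_pct,
                          sub_seed(seed, k))
    st[[turn]] <- staircase_step(st[[turn]], r)
    turn <- 3L - turn
  }
  st <- lapply(st, function(s) {
    s$converged_level_pct <- staircase_converged_level(s)
    s
  })
  stair_level <- mean(vapply(st, `[[`, numeric(1), "converged_level_pct"))

  bias <- flicker_bias_staircase(obs, seed = sub_seed(seed, 1001L))
  q <- quest_run(obs, seed = sub_seed(seed, 2002L),
                 start_level_pct = stair_level)
  v <- verify_titration(obs, q$estimate_pct, quest_margin = q$sd_pct,
                        seed = sub_seed(seed, 3003L))
  if (v$rerun) {
    v <- verify_titration(obs, v$adjusted_contrast_pct,
                          quest_margin = q$sd_pct,
                          seed = sub_seed(seed, 4004L))
  }
  list(staircases = st, stair_level_pct = stair_level,
       flicker_bias = bias, quest = q, verification = v,
       contrast_diff_pct = v$adjusted_contrast_pct)
}
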