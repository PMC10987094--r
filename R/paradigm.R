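#' @keywords internal
"_PACKAGE"

# Timing constants for the trial structure (ms). The display runs at 100 Hz,
# so all stimulus timing is quantised to 10 ms frames.
FRAME_MS <- 10
FADE_MS <- 400
BASELINE_MS <- 800
EVIDENCE_MS <- 2000
PULSE_MS <- 150
RESPONSE_DEADLINE_MS <- 1800
BLOCK_LENGTH <- 48

CUE_LEVELS <- c("valid", "invalid", "neutral")
TILT_LEVELS <- c("left", "right")
PULSE_LEVELS <- c("none", "reverse", "gap", "positive")
TAG_FREQS <- c(20, 25)

#' Pulse onset times
#'
#' The five possible evidence-pulse onset times: the first begins 180 ms
#' after evidence onset and the rest are staggered in 80 ms increments up to
#' 500 ms.
#'
#' @return Integer vector of five strictly increasing onset times (ms).
#' @export
#' @examples
#' pulse_onsets()
pulse_onsets <- function() {
  seq(180L, 500L, by = 80L)
}

#' Generate a session trial schedule
#'
#' Builds a randomised trial schedule for the two-alternative forced-choice
#' contrast discrimination task. Cues follow the 4:1:1
#' valid:invalid:neutral composition (valid cues are four times as frequent
#' as invalid cues, making directional cues 80% predictive; invalid and
#' neutral cues are equally frequent). The 16 pulse conditions (3 pulse
#' types x 5 onsets, plus no pulse) are equally represented, and the
#' assignment of the 20/25 Hz tag frequency to the target grating is
#' counterbalanced within every cue x pulse cell. The starting spatial
#' phase of the gratings alternates by a half cycle from trial to trial.
#'
#' @param n_trials Number of trials; must be at least 16 so every pulse
#'   condition can be represented. Sessions come in a long (~1152 trials)
#'   and short (~768 trials) variant.
#' @param long_session Logical; if `n_trials` is missing, selects 1152
#'   (long) or 768 (short) trials.
#' @param seed Integer seed; the schedule is deterministic given the seed.
#' @param marginal_contrast_pct Contrast divergence of the target grating
#'   from the 50% baseline (target at `50 + marginal_contrast_pct`,
#'   non-target at `50 - marginal_contrast_pct`), as set by the session's
#'   calibration. Must leave positive pulses within the physical [0, 100]
#'   contrast range (i.e. at most 25).
#' @param session_index Session label recorded on every trial.
#'
#' @return A data frame with class `trial_schedule`, one row per trial:
#'   `session_index`, `trial_index`, `block`, `cue`, `target_tilt`,
#'   `target_tag_hz`, `pulse_type`, `pulse_onset_ms` (NA when no pulse),
#'   `pulse_duration_ms`, `marginal_contrast_pct`, `start_phase_half_cycles`,
#'   `immutable`.
#' @export
generate_session <- function(n_trials = NULL, long_session = FALSE, seed = 1L,
                             marginal_contrast_pct = 15,
                             session_index = 1L) {
  if (is.null(n_trials)) n_trials <- if (long_session) 1152L else 768L
  n_trials <- as.integer(n_trials)
  if (n_trials < 16L) {
    stop("n_trials must be at least 16 to represent every pulse condition")
  }
  if (marginal_contrast_pct < 0 || marginal_contrast_pct > 25) {
    stop("marginal_contrast_pct must lie in [0, 25] so that positive pulses ",
         "remain within the [0, 100] contrast range")
  }

  rng <- local_rng(seed)

  # 16 pulse cells: none + 3 types x 5 onsets, each as close to n/16 as
  # possible (exact when n_trials is a multiple of 16).
  cells <- data.frame(
    pulse_type = c("none", rep(c("reverse", "gap", "positive"), each = 5L)),
    pulse_onset_ms = c(NA_integer_, rep(pulse_onsets(), times = 3L)),
    stringsAsFactors = FALSE
  )
  base <- n_trials %/% 16L
  extra <- n_trials %% 16L
  cell_n <- rep(base, 16L)
  if (extra > 0L) cell_n[sample(16L, extra)] <- base + 1L

  sched <- data.frame(
    pulse_type = rep(cells$pulse_type, times = cell_n),
    pulse_onset_ms = rep(cells$pulse_onset_ms, times = cell_n),
    stringsAsFactors = FALSE
  )

  # session-level cue composition (4:1:1, remainder to valid), dealt over
  # the cell-major trial list in a repeating v,v,v,v,i,n pattern so every
  # pulse cell receives a near-identical cue mix
  counts <- cue_composition(n_trials)
  pattern <- rep_len(c("valid", "valid", "valid", "valid", "invalid",
                       "neutral"), n_trials)
  # trim the pattern to the exact composition (remainder goes to valid)
  for (cu in c("invalid", "neutral")) {
    excess <- sum(pattern == cu) - counts[[cu]]
    if (excess > 0) {
      pattern[utils::tail(which(pattern == cu), excess)] <- "valid"
    }
  }
  sched$cue <- pattern

  # tag frequency and tilt counterbalanced within every cue x pulse cell
  sched$target_tag_hz <- NA_real_
  sched$target_tilt <- NA_character_
  shuffle <- function(x) x[sample.int(length(x))]
  grp <- paste(sched$cue, sched$pulse_type, sched$pulse_onset_ms)
  for (g in unique(grp)) {
    idx <- which(grp == g)
    m <- length(idx)
    sched$target_tag_hz[idx] <- shuffle(rep_len(shuffle(TAG_FREQS), m))
    sched$target_tilt[idx] <- shuffle(rep_len(shuffle(TILT_LEVELS), m))
  }

  # Randomise presentation order of the cell-expanded list.
  sched <- sched[sample(nrow(sched)), , drop = FALSE]
  n <- nrow(sched)
  sched$session_index <- as.integer(session_index)
  sched$trial_index <- seq_len(n)
  sched$block <- ((seq_len(n) - 1L) %/% BLOCK_LENGTH) + 1L
  sched$pulse_duration_ms <- PULSE_MS
  sched$marginal_contrast_pct <- marginal_contrast_pct
  sched$start_phase_half_cycles <- seq_len(n) %% 2L
  sched$immutable <- FALSE
  rownames(sched) <- NULL
  sched <- sched[, c("session_index", "trial_index", "block", "cue",
                     "target_tilt", "target_tag_hz", "pulse_type",
                     "pulse_onset_ms", "pulse_duration_ms",
                     "marginal_contrast_pct", "start_phase_half_cycles",
                     "immutable")]
  class(sched) <- c("trial_schedule", "data.frame")
  sched
}

# Largest composition preserving valid = 4 x invalid, invalid = neutral,
# with the remainder assigned to valid (keeps directional cues ~80%
# predictive as n grows).
cue_composition <- function(n) {
  unit <- n %/% 6L
  rem <- n - 6L * unit
  c(valid = 4L * unit + rem, invalid = unit, neutral = unit)
}

#' Per-grating contrast time course for one trial
#'
#' Builds the frame-accurate (100 Hz) contrast time course of the target and
#' non-target gratings: a 400 ms fade-in where both gratings rise
#' monotonically from 0% to 50% contrast, an 800 ms baseline at 50%, and a
#' 2000 ms evidence phase where the target steps to
#' `50 + marginal_contrast_pct` and the non-target to
#' `50 - marginal_contrast_pct`. Contrast divergences from 50% are always
#' reciprocal, so the two contrasts sum to 100 throughout baseline and
#' evidence. Evidence pulses last 150 ms with instantaneous onset and
#' offset: a reverse pulse flips the evidence to favour the other grating, a
#' gap pulse sets both gratings to 50%, and a positive pulse adds the
#' contrast differential to the target and subtracts it from the non-target
#' (e.g. 60/40 becomes 80/20).
#'
#' @param trial One row of a [generate_session()] schedule (or any list with
#'   fields `pulse_type`, `pulse_onset_ms`, `marginal_contrast_pct`).
#'
#' @return A list with class `contrast_timecourse`: `time_ms` (frame onsets,
#'   0 = fade-in start), `contrast_target_pct`, `contrast_nontarget_pct`,
#'   and `phase_markers` (onsets of fade-in, baseline, evidence, in ms).
#' @export
contrast_timecourse <- function(trial) {
  m <- trial$marginal_contrast_pct
  pt <- as.character(trial$pulse_type)
  if (pt == "positive" && (50 + 2 * m > 100 || 50 - 2 * m < 0)) {
    stop("infeasible marginal contrast for positive pulse: ",
         "doubled differential leaves [0, 100]")
  }

  total_ms <- FADE_MS + BASELINE_MS + EVIDENCE_MS
  time_ms <- seq(0L, total_ms - FRAME_MS, by = FRAME_MS)
  n_fade <- FADE_MS %/% FRAME_MS

  tgt <- numeric(length(time_ms))
  ntg <- numeric(length(time_ms))
  fade_idx <- seq_len(n_fade)
  fade_level <- 50 * seq_len(n_fade) / n_fade   # strictly rising, ends at 50
  tgt[fade_idx] <- fade_level
  ntg[fade_idx] <- fade_level
  base_idx <- which(time_ms >= FADE_MS & time_ms < FADE_MS + BASELINE_MS)
  tgt[base_idx] <- 50
  ntg[base_idx] <- 50
  ev_idx <- which(time_ms >= FADE_MS + BASELINE_MS)
  tgt[ev_idx] <- 50 + m
  ntg[ev_idx] <- 50 - m

  if (pt != "none") {
    onset <- snap_frame(trial$pulse_onset_ms) + FADE_MS + BASELINE_MS
    offset <- onset + snap_frame(PULSE_MS)
    p_idx <- which(time_ms >= onset & time_ms < offset)
    if (pt == "reverse") {
      tgt[p_idx] <- 50 - m
      ntg[p_idx] <- 50 + m
    } else if (pt == "gap") {
      tgt[p_idx] <- 50
      ntg[p_idx] <- 50
    } else if (pt == "positive") {
      tgt[p_idx] <- 50 + 2 * m
      ntg[p_idx] <- 50 - 2 * m
    }
  }

  structure(
    list(time_ms = time_ms,
         contrast_target_pct = tgt,
         contrast_nontarget_pct = ntg,
         phase_markers = c(fade_in = 0L, baseline = FADE_MS,
                           evidence = FADE_MS + BASELINE_MS)),
    class = "contrast_timecourse"
  )
}

snap_frame <- function(ms) FRAME_MS * round(ms / FRAME_MS)

#' Apply the trial-replacement mechanism
#'
#' Re-presents trials on which the participant responded too early. A
#' response before evidence onset appends an exact replica of the trial to
#' the end of its block. A response before the pulse onset of a pulse trial
#' feeds the extra block at the end of the session: the first such response
#' adds a set of three trials (a replica marked immutable, plus two mutable
#' trials with a different cue x pulse-onset combination drawn uniformly
#' without replacement from the remaining alternatives); subsequent
#' pre-pulse responses swap a mutable extra-block trial for a replica when
#' one is available, and a fresh set of three is added when no mutable trial
#' remains or when more than 20% of the extra block shares a single pulse
#' type.
#'
#' @param schedule A `trial_schedule` data frame.
#' @param responses Data frame of early-response events with columns
#'   `trial_index` and `rt_ms` (response time relative to evidence onset;
#'   negative values are responses before evidence onset). Responses at or
#'   after evidence onset but before a trial's pulse onset trigger the
#'   extra-block mechanism; all other rows are ignored.
#' @param seed Integer seed for sampling the alternative conditions.
#'
#' @return The augmented `trial_schedule`. With no early responses the
#'   input is returned unchanged.
#' @export
apply_replacement <- function(schedule, responses, seed = 1L) {
  if (is.null(responses) || nrow(responses) == 0L) return(schedule)
  rng <- local_rng(seed)

  extra_block_id <- max(schedule$block) + 1L
  extra <- schedule[0, , drop = FALSE]
  appended <- schedule[0, , drop = FALSE]

  responses <- responses[order(responses$trial_index), , drop = FALSE]
  for (i in seq_len(nrow(responses))) {
    k <- responses$trial_index[i]
    rt <- responses$rt_ms[i]
    row <- schedule[schedule$trial_index == k, , drop = FALSE]
    if (nrow(row) != 1L) stop("response refers to unknown trial_index ", k)

    if (rt < 0) {
      # Before evidence onset: exact replica at the end of the current block.
      rep_row <- row
      rep_row$immutable <- FALSE
      # sort key pushes replicas past every original trial of the block
      rep_row$trial_index <- rep_row$trial_index + nrow(schedule) + i
      appended <- rbind(appended, rep_row)
    } else if (row$pulse_type != "none" && rt < row$pulse_onset_ms) {
      mutable <- which(!extra$immutable)
      # share of the incoming replica's pulse type in the extra block:
      # above 20%, a fresh set of three is added instead of swapping
      share <- if (nrow(extra) > 0L) {
        mean(extra$pulse_type == row$pulse_type)
      } else 0
      if (length(mutable) > 0L && share <= 0.2) {
        swap <- mutable[1L]
        rep_row <- row
        rep_row$immutable <- TRUE
        rep_row$block <- extra_block_id
        extra[swap, ] <- rep_row
      } else {
        extra <- rbind(extra, replacement_triple(row, extra_block_id))
      }
    }
  }

  out <- rbind(schedule, appended, extra)
  # Replicas belong to the block of their source trial; keep block ordering.
  out <- out[order(out$block, out$trial_index), , drop = FALSE]
  out$trial_index <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("trial_schedule", "data.frame")
  out
}

# A replica (immutable) plus two mutable trials with different cue x
# pulse-onset combinations, sampled uniformly without replacement from the
# remaining alternatives.
replacement_triple <- function(row, extra_block_id) {
  rep_row <- row
  rep_row$immutable <- TRUE
  rep_row$block <- extra_block_id

  combos <- expand.grid(cue = CUE_LEVELS, pulse_onset_ms = pulse_onsets(),
                        stringsAsFactors = FALSE)
  keep <- !(combos$cue == row$cue & combos$pulse_onset_ms == row$pulse_onset_ms)
  combos <- combos[keep, , drop = FALSE]
  pick <- combos[sample(nrow(combos), 2L), , drop = FALSE]

  alts <- row[rep(1L, 2L), , drop = FALSE]
  alts$cue <- pick$cue
  alts$pulse_onset_ms <- pick$pulse_onset_ms
  alts$immutable <- FALSE
  alts$block <- extra_block_id
  rbind(rep_row, alts)
}

#' Score a single response
#'
#' Correct responses inside the response window earn +50 points; errors lose
#' 25 points. A response before evidence onset ("too fast") or no response
#' within the deadline ("too slow") also loses 25 points.
#'
#' @param correct Logical; was the chosen grating the higher-contrast one?
#' @param rt_ms Response time in ms relative to evidence onset; `NA` or
#'   missing means no response.
#' @param deadline_ms Response deadline (default 1800 ms).
#'
#' @return A list with class `feedback_outcome`: `points_delta` (+50 or -25)
#'   and `outcome` (`"correct"`, `"error"`, `"too_fast"`, `"too_slow"`).
#' @export
score_response <- function(correct, rt_ms = NA_real_,
                           deadline_ms = RESPONSE_DEADLINE_MS) {
  outcome <-
    if (is.na(rt_ms)) "too_slow"
    else if (rt_ms < 0) "too_fast"
    else if (rt_ms > deadline_ms) "too_slow"
    else if (isTRUE(correct)) "correct"
    else "error"
  structure(
    list(points_delta = if (outcome == "correct") 50L else -25L,
         outcome = outcome),
    class = "feedback_outcome"
  )
}

#' Write / read a trial schedule as CSV
#'
#' @param schedule A `trial_schedule`.
#' @param path Output CSV path.
#' @return `path`, invisibly (`write_schedule`); the schedule
#'   (`read_schedule`).
#' @export
write_schedule <- function(schedule, path) {
  utils::write.csv(as.data.frame(schedule), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  sched <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(sched) <- c("trial_schedule", "data.frame")
  sched
}

# Seed the RNG for a stochastic operation. Seeds derived from a base seed
# stay below 2^31 - 1.
local_rng <- function(seed) {
  set.seed(as.integer(seed %% 2147483647))
  invisible(NULL)
}

# Derive a stream-specific sub-seed from a base seed.
sub_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + stream) %% 2147483647)
}
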