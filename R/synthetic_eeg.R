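# Synthetic multichannel EEG with known ground truth: frequency-tagged
# SSVEPs that track the grating contrast time course, lateralised mu-beta,
# occipito-parietal alpha, 1/f background noise, and blink artifacts on the
# VEOG pair.

FS_HZ <- 512

#' Generator parameters for synthetic EEG
#'
#' Defaults describe a desk-scale recording: a 35-channel scalp montage
#' plus two VEOG channels at 512 Hz. The SSVEP forward model is linear in
#' contrast: each grating contributes a sinusoid at its tag frequency whose
#' instantaneous amplitude is `ssvep_gain` (uV per % contrast) times the
#' grating's contrast, modulated per cue condition via
#' `cue_evidence_gain` (a gain on the contrast *differential*, so a gain of
#' 0.9 on invalid-cue trials shrinks the marginal SSVEP by 10%). With
#' `cue_gain_exposure_ramp = TRUE` the differential gain moves linearly
#' from 1 (no effect) at the start of testing to its nominal value at the
#' end, emulating an effect that emerges with task exposure.
#'
#' @param montage A [default_montage()].
#' @param ssvep_gain SSVEP amplitude per unit contrast (uV per %).
#' @param cue_evidence_gain Named gain on the contrast differential by cue
#'   (`valid`, `invalid`, `neutral`).
#' @param cue_gain_exposure_ramp Ramp the cue gain with task exposure?
#' @param mb_amplitude_uv Baseline mu-beta amplitude per hemisphere.
#' @param mb_lateralization Pre-evidence amplitude reduction (uV)
#'   contralateral to the cued response on directional-cue trials.
#' @param mb_response_desync Additional desynchronisation (uV) contralateral
#'   to the executed response, ramping over the 400 ms before the response.
#' @param alpha_engagement Named alpha amplitude (uV) by cue condition;
#'   lower amplitude means stronger desynchronisation (greater engagement).
#' @param noise_rms_uv RMS of the 1/f background noise per channel.
#' @param noise_exponent Spectral slope of the background (power ~ 1/f^a).
#' @param blink_rate_hz Poisson rate of blinks.
#' @param blink_amplitude_uv Blink peak on the upper VEOG channel (above
#'   250 uV by default so threshold rejection is exercised).
#' @param seed Base seed; per-trial seeds are derived from it.
#' @return A list with class `gen_params`.
#' @export
gen_params <- function(montage = default_montage(),
                       ssvep_gain = 0.05,
                       cue_evidence_gain = c(valid = 1, invalid = 1,
                                             neutral = 1),
                       cue_gain_exposure_ramp = FALSE,
                       mb_amplitude_uv = 4,
                       mb_lateralization = 1,
                       mb_response_desync = 1.5,
                       alpha_engagement = c(valid = 3, invalid = 3,
                                            neutral = 2.4),
                       noise_rms_uv = 3,
                       noise_exponent = 1,
                       blink_rate_hz = 0.03,
                       blink_amplitude_uv = 300,
                       seed = 1L) {
  stopifnot(ssvep_gain >= 0, mb_amplitude_uv >= 0, noise_rms_uv >= 0,
            all(cue_evidence_gain >= 0), all(alpha_engagement >= 0))
  structure(
    list(montage = montage, fs_hz = FS_HZ, ssvep_gain = ssvep_gain,
         cue_evidence_gain = cue_evidence_gain,
         cue_gain_exposure_ramp = cue_gain_exposure_ramp,
         mb_amplitude_uv = mb_amplitude_uv,
         mb_lateralization = mb_lateralization,
         mb_response_desync = mb_response_desync,
         alpha_engagement = alpha_engagement,
         noise_rms_uv = noise_rms_uv, noise_exponent = noise_exponent,
         blink_rate_hz = blink_rate_hz,
         blink_amplitude_uv = blink_amplitude_uv,
         seed = as.integer(seed)),
    class = "gen_params"
  )
}

#' Construct an EEG epoch container
#'
#' @param data Channels x samples matrix (uV).
#' @param t_ms Sample times in ms relative to the alignment event.
#' @param montage A [default_montage()].
#' @param alignment One of `"cue"`, `"evidence"`, `"response"`,
#'   `"continuous"`.
#' @param trial Optional list/row of trial metadata.
#' @return A list with class `eeg_epoch`.
#' @export
eeg_epoch <- function(data, t_ms, montage, alignment = "continuous",
                      trial = NULL) {
  stopifnot(nrow(data) == nrow(montage), ncol(data) == length(t_ms),
            all(is.finite(data)))
  rownames(data) <- montage$label
  structure(
    list(data = data, fs_hz = FS_HZ, t_ms = t_ms, t0_ms = t_ms[1],
         alignment = alignment, channel_labels = montage$label,
         montage = montage, trial = trial),
    class = "eeg_epoch"
  )
}

# Sample grid (ms, relative to evidence onset) covering the full trial:
# fade-in through the end of evidence presentation.
trial_sample_times <- function() {
  k <- seq(ceiling(-1700 * FS_HZ / 1000), ceiling(2000 * FS_HZ / 1000) - 1L)
  k * 1000 / FS_HZ
}

# Gaussian spatial weight around a peak electrode (angular distance on the
# unit sphere); VEOG channels get weight 0.
topo_weights <- function(montage, peak_label, width_rad = 0.6) {
  p <- montage[montage$label == peak_label, ]
  xyz <- as.matrix(montage[, c("x", "y", "z")])
  cosang <- xyz %*% c(p$x, p$y, p$z)
  w <- exp(-(acos(pmin(1, pmax(-1, cosang))) / width_rad)^2)
  w[!montage$is_scalp] <- 0
  w[is.na(w)] <- 0
  as.numeric(w)
}

# 1/f noise: white Gaussian shaped in the frequency domain to power ~
# 1/f^a, scaled to the requested RMS.
one_over_f_noise <- function(n, rms, exponent) {
  if (rms == 0) return(numeric(n))
  white <- stats::rnorm(n)
  sp <- stats::fft(white)
  f <- c(1e-3, seq_len(n - 1)) * FS_HZ / n
  f <- pmin(f, FS_HZ - f + 1e-9)     # two-sided axis
  shape <- 1 / f^(exponent / 2)
  shape[1] <- 0                       # no DC drift component
  x <- Re(stats::fft(sp * shape, inverse = TRUE)) / n
  x * rms / stats::sd(x)
}

# Raised-cosine blink waveform (~240 ms).
blink_waveform <- function() {
  n <- round(0.24 * FS_HZ)
  0.5 * (1 - cos(2 * pi * seq_len(n) / n))
}

# Hand contralateral to a tilt/response side: left response -> right
# hemisphere preparation.
contra_hemisphere <- function(side) if (side == "left") "right" else "left"

#' Simulate the EEG of one trial
#'
#' Forward model, summed at the sensors: (1) for each grating a
#' phase-reversal SSVEP carrier at its tag frequency with instantaneous
#' amplitude `ssvep_gain x contrast(t)`, focused over occipital channels,
#' where the evidence-phase contrast differential is scaled by the cue's
#' `cue_evidence_gain` (optionally ramped with task exposure); (2) mu-beta
#' oscillations over each central region whose amplitude drops
#' contralaterally to the cued response after cue onset
#' (`mb_lateralization`) and contralaterally to the executed response over
#' the 400 ms preceding it (`mb_response_desync`); (3) alpha over
#' occipito-parietal midline sites with amplitude `alpha_engagement[cue]`;
#' (4) 1/f background noise on every channel; (5) Poisson blinks on the
#' VEOG pair propagating to frontal channels. Deterministic given
#' `params$seed` and the trial index.
#'
#' @param trial One row of a [generate_session()] schedule.
#' @param timecourse The trial's [contrast_timecourse()].
#' @param params A [gen_params()].
#' @param rt_ms Response time (ms after evidence onset) used to place the
#'   response-locked motor desynchronisation.
#' @param response_side `"left"` or `"right"` executed response.
#' @param exposure_frac Task-exposure fraction in \[0, 1\] used by the cue
#'   gain ramp.
#' @return An `eeg_epoch` spanning -1700 to 2000 ms around evidence onset
#'   (alignment `"continuous"`).
#' @export
simulate_trial_eeg <- function(trial, timecourse = contrast_timecourse(trial),
                               params = gen_params(), rt_ms = 900,
                               response_side = trial$target_tilt,
                               exposure_frac = 0) {
  local_rng(sub_seed(params$seed, trial$trial_index))
  mont <- params$montage
  n_ch <- nrow(mont)
  t_ms <- trial_sample_times()
  n <- length(t_ms)
  X <- matrix(0, n_ch, n)

  cue <- as.character(trial$cue)
  gain <- params$cue_evidence_gain[[cue]]
  if (isTRUE(params$cue_gain_exposure_ramp)) {
    gain <- 1 + (gain - 1) * exposure_frac
  }

  # per-grating contrast sampled onto the EEG grid (zero-order hold from
  # the 100 Hz frame grid; zero before fade-in onset at -1200 ms)
  contrast_at <- function(contrast_frames) {
    tc_t <- timecourse$time_ms - 1200   # frame onsets rel. evidence onset
    idx <- findInterval(t_ms, tc_t)
    out <- numeric(n)
    inside <- idx >= 1 & idx <= length(contrast_frames)
    out[inside] <- contrast_frames[idx[inside]]
    # stimulus holds its final contrast past the last frame
    out[idx > length(contrast_frames)] <-
      contrast_frames[length(contrast_frames)]
    out
  }
  scale_diff <- function(c_pct) 50 + (c_pct - 50) * gain
  c_tgt <- scale_diff(contrast_at(timecourse$contrast_target_pct))
  c_ntg <- scale_diff(contrast_at(timecourse$contrast_nontarget_pct))

  # SSVEP carriers (phase-reversal fundamental at the tag frequency); the
  # starting phase alternates by a half cycle across trials
  w_ssvep <- topo_weights(mont, "Oz", 0.5)
  phase0 <- pi * trial$start_phase_half_cycles
  f_tgt <- trial$target_tag_hz
  f_ntg <- setdiff(TAG_FREQS, f_tgt)
  ssvep <- params$ssvep_gain * (
    c_tgt * sin(2 * pi * f_tgt * t_ms / 1000 + phase0) +
    c_ntg * sin(2 * pi * f_ntg * t_ms / 1000 + phase0)
  )
  X <- X + w_ssvep %o% ssvep

  # mu-beta: fixed set of 8-30 Hz components away from the tag bins
  mb_freqs <- c(10, 12.5, 15, 17.5, 22.5, 27.5)
  mb_osc <- function() {
    ph <- stats::runif(length(mb_freqs), 0, 2 * pi)
    rowSums(vapply(seq_along(mb_freqs), function(i)
      sin(2 * pi * mb_freqs[i] * t_ms / 1000 + ph[i]), numeric(n))) /
      sqrt(length(mb_freqs))
  }
  cue_side <- if (cue == "valid") trial$target_tilt
              else if (cue == "invalid") contra_hemisphere(trial$target_tilt)
              else NA_character_
  for (hemi in c("left", "right")) {
    amp <- rep(params$mb_amplitude_uv, n)
    if (!is.na(cue_side) && hemi == contra_hemisphere(cue_side)) {
      amp <- amp - params$mb_lateralization * (t_ms >= -1200)
    }
    if (hemi == contra_hemisphere(response_side)) {
      ramp <- pmin(1, pmax(0, (t_ms - (rt_ms - 400)) / 400))
      amp <- amp - params$mb_response_desync * ramp
    }
    w <- topo_weights(mont, if (hemi == "left") "C3" else "C4", 0.45)
    X <- X + w %o% (pmax(0, amp) * mb_osc())
  }

  # alpha over occipito-parietal midline, amplitude set by cue condition
  w_alpha <- topo_weights(mont, "POz", 0.5)
  alpha_amp <- params$alpha_engagement[[cue]]
  X <- X + w_alpha %o% (alpha_amp * sin(2 * pi * 10 * t_ms / 1000 +
                                        stats::runif(1, 0, 2 * pi)))

  # 1/f background on every channel (including VEOG)
  if (params$noise_rms_uv > 0) {
    for (ch in seq_len(n_ch)) {
      X[ch, ] <- X[ch, ] + one_over_f_noise(n, params$noise_rms_uv,
                                            params$noise_exponent)
    }
  }

  # blinks: Poisson events on the VEOG pair with frontal propagation
  if (params$blink_rate_hz > 0 && params$blink_amplitude_uv > 0) {
    dur_s <- n / FS_HZ
    n_blinks <- stats::rpois(1, params$blink_rate_hz * dur_s)
    if (n_blinks > 0) {
      bw <- blink_waveform() * params$blink_amplitude_uv
      iu <- which(mont$label == "VEOGupper")
      il <- which(mont$label == "VEOGlower")
      w_front <- topo_weights(mont, "Fp1", 0.5) +
                 topo_weights(mont, "Fp2", 0.5)
      for (b in seq_len(n_blinks)) {
        s0 <- sample.int(n - length(bw), 1)
        idx <- s0 + seq_along(bw) - 1L
        X[iu, idx] <- X[iu, idx] + bw
        X[il, idx] <- X[il, idx] - 0.4 * bw
        X[, idx] <- X[, idx] + 0.15 * (w_front %o% bw)
      }
    }
  }

  tr <- as.list(trial)
  tr$rt_ms <- rt_ms
  tr$response_side <- response_side
  tr$exposure_frac <- exposure_frac
  eeg_epoch(X, t_ms, mont, alignment = "continuous", trial = tr)
}

#' Simulate per-trial behaviour
#'
#' Accuracy is drawn from a Bernoulli whose probability is the base 70%
#' rate shifted on the logit scale by cue condition (defaults +0.184 for
#' valid, -0.219 for invalid, relative to neutral). Reaction time is drawn
#' from a shifted lognormal with additive cue shifts that differ for
#' correct and error responses (defaults, in seconds: correct
#' valid -0.043 / invalid +0.085; error valid +0.084 / invalid -0.047,
#' relative to neutral).
#'
#' @param trial One row of a [generate_session()] schedule.
#' @param behav_params Optional overrides: `base_p_correct`,
#'   `acc_logit_shift` (named), `rt_shift_s` (named for
#'   `correct_valid`, `correct_invalid`, `error_valid`, `error_invalid`),
#'   `rt_meanlog`, `rt_sdlog`, `rt_shift_floor_s`.
#' @param seed Integer seed.
#' @return A list: `rt_s`, `correct`, `response_side`.
#' @export
simulate_behaviour <- function(trial, behav_params = list(), seed = 1L) {
  p <- utils::modifyList(list(
    base_p_correct = 0.70,
    acc_logit_shift = c(valid = 0.184, invalid = -0.219, neutral = 0),
    rt_shift_s = c(correct_valid = -0.043, correct_invalid = 0.085,
                   error_valid = 0.084, error_invalid = -0.047,
                   correct_neutral = 0, error_neutral = 0),
    rt_meanlog = log(0.65) - 0.35^2 / 2,
    rt_sdlog = 0.35,
    rt_shift_floor_s = 0.25
  ), behav_params)
  local_rng(seed)
  cue <- as.character(trial$cue)
  pc <- stats::plogis(stats::qlogis(p$base_p_correct) +
                      p$acc_logit_shift[[cue]])
  correct <- stats::runif(1) < pc
  key <- paste0(if (correct) "correct_" else "error_", cue)
  rt <- p$rt_shift_floor_s + stats::rlnorm(1, p$rt_meanlog, p$rt_sdlog) +
    p$rt_shift_s[[key]]
  rt <- max(rt, 0.15)
  response_side <- if (correct) trial$target_tilt
                   else contra_hemisphere(trial$target_tilt)
  list(rt_s = rt, correct = correct, response_side = response_side)
}

#' Simulate a dataset of sessions to disk
#'
#' Writes, per subject and session, a trial table CSV (schedule plus
#' simulated behaviour, keyed by `trial_uid`), an epochs container (RDS
#' list of `eeg_epoch`s), and a dataset-level `manifest.json` recording
#' every injected generator parameter as ground truth.
#'
#' @param n_subjects,sessions_per_subject,trials_per_session Dataset size.
#' @param params A [gen_params()].
#' @param behav_params Passed to [simulate_behaviour()].
#' @param seed Base seed (trial tables regenerate byte-identically).
#' @param dir Output directory.
#' @param write_epochs Write the EEG containers (skip for behaviour-only
#'   datasets).
#' @return `dir`, invisibly.
#' @export
make_dataset <- function(n_subjects = 2, sessions_per_subject = 1,
                         trials_per_session = 64,
                         params = gen_params(), behav_params = list(),
                         seed = 1L, dir = tempfile("ssvepcue_data_"),
                         write_epochs = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  total_sessions <- sessions_per_subject
  for (s in seq_len(n_subjects)) {
    for (ses in seq_len(sessions_per_subject)) {
      sched <- generate_session(trials_per_session,
                                seed = sub_seed(seed, s * 1000L + ses),
                                session_index = ses)
      sched$subject_id <- sprintf("S%02d", s)
      sched$trial_uid <- sprintf("S%02d_%02d_%04d", s, ses,
                                 sched$trial_index)
      n <- nrow(sched)
      beh <- lapply(seq_len(n), function(i)
        simulate_behaviour(sched[i, ], behav_params,
                           seed = sub_seed(seed, s * 100000L + ses * 10000L + i)))
      sched$rt_s <- vapply(beh, `[[`, numeric(1), "rt_s")
      sched$correct <- vapply(beh, `[[`, logical(1), "correct")
      sched$response_side <- vapply(beh, `[[`, character(1), "response_side")
      sched$exposure_frac <- ((ses - 1) * n + seq_len(n) - 1) /
        max(1, total_sessions * n - 1)
      base <- file.path(dir, sprintf("S%02d_ses%02d", s, ses))
      utils::write.csv(as.data.frame(sched), paste0(base, "_trials.csv"),
                       row.names = FALSE)
      if (write_epochs) {
        epochs <- lapply(seq_len(n), function(i) {
          tr <- sched[i, ]
          simulate_trial_eeg(tr, contrast_timecourse(tr), params,
                             rt_ms = tr$rt_s * 1000,
                             response_side = tr$response_side,
                             exposure_frac = tr$exposure_frac)
        })
        saveRDS(epochs, paste0(base, "_epochs.rds"))
        meta <- list(fs_hz = FS_HZ, n_trials = n,
                     channel_labels = params$montage$label,
                     alignment = "continuous",
                     t0_ms = trial_sample_times()[1])
        jsonlite::write_json(meta, paste0(base, "_epochs.json"),
                             auto_unbox = TRUE, digits = NA)
      }
    }
  }
  manifest <- list(
    n_subjects = n_subjects, sessions_per_subject = sessions_per_subject,
    trials_per_session = trials_per_session, seed = seed,
    params = params[setdiff(names(params), "montage")],
    behav_params = behav_params,
    n_channels = nrow(params$montage)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
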