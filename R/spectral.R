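# Short-time Fourier amplitude extraction (rectangular taper), neighbour-
# bin SSVEP normalisation, mu-beta and alpha band measures, and the
# data-driven electrode selection rules.

SSVEP_WINDOW_MS <- 400
ALPHA_WINDOW_MS <- 360
STFT_STEP_MS <- 50
MB_BAND_HZ <- c(8, 30)
ALPHA_BAND_HZ <- c(8, 14)

#' Short-time Fourier amplitude of an epoch
#'
#' Slides a rectangular window along the epoch in 50 ms steps and returns
#' the single-sided DFT amplitude spectrum of the channel-combined signal,
#' scaled so a unit-amplitude sinusoid at an exact bin frequency yields 1.
#' Each estimate is mapped to the midpoint of its window, and window
#' midpoints lie on the 50 ms grid anchored at the epoch's alignment event
#' (t = 0). The nominal window length is realised as
#' `round(window_ms * fs / 1000)` samples (205 for the 400 ms window at
#' 512 Hz), so the bin spacing is `fs / n_samples` -- 2.4976 Hz for the
#' 400 ms window, placing the 20/25 Hz tags within 0.025 Hz of bin
#' centres. An estimate at time t uses only samples in
#' `[t - w/2, t + w/2)` where w is the realised window length.
#'
#' @param epoch An `eeg_epoch`.
#' @param channels Channel labels to combine (default: all scalp).
#' @param window_ms Nominal window length, ms (400 for SSVEP/mu-beta, 360
#'   for alpha).
#' @param step_ms Step between window midpoints (50 ms).
#' @param combine Combine channels `"before"` the DFT (average the
#'   time-domain signals) or `"after"` (average the per-channel amplitude
#'   spectra).
#' @return A list with class `spectral_estimate`: `amplitude` (time x
#'   frequency matrix, uV), `times_ms` (window midpoints), `freqs_hz`
#'   (bin centres), `window_ms`, `step_ms`, `n_window_samples`.
#' @export
stft_amplitude <- function(epoch, channels = NULL,
                           window_ms = SSVEP_WINDOW_MS,
                           step_ms = STFT_STEP_MS,
                           combine = c("before", "after")) {
  combine <- match.arg(combine)
  if (is.null(channels)) {
    channels <- epoch$montage$label[epoch$montage$is_scalp]
  }
  idx <- match(channels, epoch$channel_labels)
  if (anyNA(idx)) stop("unknown channel label(s): ",
                       paste(channels[is.na(idx)], collapse = ", "))
  n_win <- round(window_ms * epoch$fs_hz / 1000)
  n <- length(epoch$t_ms)
  if (n_win > n) stop("window_ms longer than the epoch")
  dt <- 1000 / epoch$fs_hz
  half <- n_win * dt / 2

  # midpoints on the 50 ms grid (anchored at the alignment event) whose
  # realised window fits inside the epoch
  mids <- seq(ceiling((epoch$t_ms[1] + half) / step_ms) * step_ms,
              floor((epoch$t_ms[n] + dt - half) / step_ms) * step_ms,
              by = step_ms)
  starts <- vapply(mids, function(t)
    which(epoch$t_ms >= t - half - 1e-9)[1], integer(1))
  ok <- !is.na(starts) & (starts + n_win - 1L) <= n
  mids <- mids[ok]; starts <- starts[ok]
  if (length(mids) == 0L) stop("window_ms longer than the usable epoch")

  freqs <- (seq_len(n_win %/% 2 + 1L) - 1L) * epoch$fs_hz / n_win
  one_channel <- function(x) {
    W <- vapply(starts, function(s) x[s + seq_len(n_win) - 1L],
                numeric(n_win))
    sp <- stats::mvfft(W)[seq_along(freqs), , drop = FALSE]
    amp <- 2 * Mod(sp) / n_win
    amp[1, ] <- amp[1, ] / 2
    if (n_win %% 2 == 0) amp[length(freqs), ] <- amp[length(freqs), ] / 2
    t(amp)
  }
  A <- if (combine == "before") {
    one_channel(colMeans(epoch$data[idx, , drop = FALSE]))
  } else {
    Reduce(`+`, lapply(idx, function(i) one_channel(epoch$data[i, ]))) /
      length(idx)
  }
  structure(
    list(amplitude = A, times_ms = mids, freqs_hz = freqs,
         window_ms = window_ms, step_ms = step_ms,
         n_window_samples = n_win),
    class = "spectral_estimate"
  )
}

# Index of the bin nearest a nominal frequency.
nearest_bin <- function(spec, f_hz) which.min(abs(spec$freqs_hz - f_hz))

#' Neighbour-bin normalised SSVEP amplitude
#'
#' Isolates the stimulus-driven signal at a tag frequency by subtracting
#' the mean amplitude of the `n_neighbours` bins on each side of the tag
#' bin (skipping the tag bin itself and the other tag's bin). The result
#' estimates the tag amplitude above the local broadband floor and may be
#' negative.
#'
#' @param spec A [stft_amplitude()] result.
#' @param tag_hz Tag frequency (20 or 25 Hz).
#' @param n_neighbours Bins per side (default 2).
#' @param reduce `"mean"` (default) or `"sum"` of the neighbouring bins.
#' @return A list with class `ssvep_series`: `times_ms`, `amplitude`.
#' @export
ssvep_normalized <- function(spec, tag_hz, n_neighbours = 2L,
                             reduce = c("mean", "sum")) {
  reduce <- match.arg(reduce)
  tag_bin <- nearest_bin(spec, tag_hz)
  other_tag <- setdiff(TAG_FREQS, tag_hz)
  other_bin <- if (length(other_tag) == 1L) {
    nearest_bin(spec, other_tag)
  } else -1L   # tag outside the 20/25 Hz pair: no co-tag to skip
  nb <- integer(0)
  for (dir in c(-1L, 1L)) {
    got <- 0L; k <- tag_bin
    while (got < n_neighbours) {
      k <- k + dir
      if (k < 1L || k > length(spec$freqs_hz)) {
        stop("neighbour range exits the spectrum")
      }
      if (k == other_bin) next
      nb <- c(nb, k); got <- got + 1L
    }
  }
  floor_amp <- if (reduce == "mean") {
    rowMeans(spec$amplitude[, nb, drop = FALSE])
  } else {
    rowSums(spec$amplitude[, nb, drop = FALSE])
  }
  structure(
    list(times_ms = spec$times_ms,
         amplitude = spec$amplitude[, tag_bin] - floor_amp),
    class = "ssvep_series"
  )
}

#' Marginal SSVEP (target minus non-target)
#'
#' @param target,nontarget `ssvep_series` for the target and non-target
#'   tag frequencies on a common time axis.
#' @return An `ssvep_series` of the difference.
#' @export
marginal_ssvep <- function(target, nontarget) {
  if (length(target$times_ms) != length(nontarget$times_ms) ||
      any(target$times_ms != nontarget$times_ms)) {
    stop("target and non-target time axes are misaligned")
  }
  structure(
    list(times_ms = target$times_ms,
         amplitude = target$amplitude - nontarget$amplitude),
    class = "ssvep_series"
  )
}

#' Mu-beta band amplitude
#'
#' Mean amplitude over the 8--30 Hz bins, excluding the two bins used to
#' extract the 20 and 25 Hz SSVEPs, so that tagged visual activity cannot
#' leak into the motor-preparation measure.
#'
#' @param spec A [stft_amplitude()] result (400 ms window) over one
#'   hemisphere's central channels.
#' @return A list with class `ssvep_series`: `times_ms`, `amplitude`.
#' @export
mu_beta_amplitude <- function(spec) {
  band <- which(spec$freqs_hz >= MB_BAND_HZ[1] &
                spec$freqs_hz <= MB_BAND_HZ[2])
  tags <- vapply(TAG_FREQS, function(f) nearest_bin(spec, f), integer(1))
  band <- setdiff(band, tags)
  structure(
    list(times_ms = spec$times_ms,
         amplitude = rowMeans(spec$amplitude[, band, drop = FALSE])),
    class = "ssvep_series"
  )
}

#' Contra/ipsilateral mu-beta for one trial
#'
#' Maps the two hemispheres' mu-beta series to contralateral and
#' ipsilateral relative to the reference side: the cued response side on
#' directional-cue trials, or the correct response side on neutral-cue
#' trials (which cannot be known before evidence onset).
#'
#' @param left_spec,right_spec [stft_amplitude()] over the left/right
#'   central electrodes.
#' @param reference_side `"left"` or `"right"` (response side referred
#'   to).
#' @return A list: `mb_contra`, `mb_ipsi` (`ssvep_series`).
#' @export
mu_beta <- function(left_spec, right_spec, reference_side) {
  l <- mu_beta_amplitude(left_spec)
  r <- mu_beta_amplitude(right_spec)
  # left-hand response is prepared by the right hemisphere
  if (reference_side == "left") list(mb_contra = r, mb_ipsi = l)
  else list(mb_contra = l, mb_ipsi = r)
}

#' Alpha band amplitude
#'
#' Mean amplitude over the 8--14 Hz bins of a 360 ms-window STFT over the
#' three occipito-parietal midline electrodes.
#'
#' @param spec A [stft_amplitude()] result with `window_ms = 360`.
#' @return A list with class `ssvep_series`: `times_ms`, `amplitude`.
#' @export
alpha_band <- function(spec) {
  band <- which(spec$freqs_hz >= ALPHA_BAND_HZ[1] &
                spec$freqs_hz <= ALPHA_BAND_HZ[2])
  structure(
    list(times_ms = spec$times_ms,
         amplitude = rowMeans(spec$amplitude[, band, drop = FALSE])),
    class = "ssvep_series"
  )
}

# Mean of a series over a closed window of midpoints [start, end] ms.
series_window_mean <- function(series, start_ms, end_ms) {
  sel <- series$times_ms >= start_ms & series$times_ms <= end_ms
  if (!any(sel)) return(NA_real_)
  mean(series$amplitude[sel])
}

#' Select SSVEP electrodes from the occipital candidate pool
#'
#' Ranks each candidate electrode by its contrast discrimination: the mean
#' target-minus-non-target normalised SSVEP amplitude in the window
#' 200:1800 ms after evidence onset, averaged over trials. The top two
#' electrodes are returned; ties break by candidate order (logged).
#'
#' @param epochs List of evidence-locked `eeg_epoch`s with trial metadata
#'   (`target_tag_hz`).
#' @param pool Candidate electrode labels (>= 2).
#' @param n_top Number of electrodes to keep.
#' @return A list: `channels` (labels), `scores`, `tie` (logical).
#' @export
select_ssvep_electrodes <- function(epochs, pool, n_top = 2L) {
  stopifnot(length(pool) >= 2L)
  scores <- vapply(pool, function(ch) {
    mean(vapply(epochs, function(e) {
      spec <- stft_amplitude(e, channels = ch)
      f_tgt <- e$trial$target_tag_hz
      f_ntg <- setdiff(TAG_FREQS, f_tgt)
      marg <- marginal_ssvep(ssvep_normalized(spec, f_tgt),
                             ssvep_normalized(spec, f_ntg))
      series_window_mean(marg, 200, 1800)
    }, numeric(1)))
  }, numeric(1))
  ord <- order(-scores, seq_along(pool))
  tie <- anyDuplicated(round(scores, 12)) > 0
  list(channels = pool[ord[seq_len(n_top)]], scores = scores, tie = tie)
}

#' Select mu-beta electrodes per hemisphere
#'
#' Scores every candidate central electrode on two criteria computed from
#' response-locked epochs: (1) the difference in mu-beta amplitude at the
#' response between trials where the electrode was ipsilateral vs
#' contralateral to the executed response (desynchronisation makes the
#' contralateral amplitude lower, so larger is better); (2) the negated
#' slope of mu-beta amplitude over the 400 ms preceding contralateral
#' responses (steeper pre-response desynchronisation is better). The two
#' criterion rankings are combined by rank sum and the top two electrodes
#' per hemisphere are returned. When no lateralised signal is present the
#' selection is still deterministic (candidate order breaks ties) but is
#' flagged low-confidence.
#'
#' @param response_epochs List of response-locked `eeg_epoch`s whose
#'   trial metadata includes `response_side`.
#' @param pools A list with `central_left`, `central_right` (see
#'   [electrode_pools()]).
#' @param n_top Electrodes per hemisphere.
#' @return A list: `left`, `right` (labels), `scores` (per-hemisphere
#'   data frames), `low_confidence`.
#' @export
select_mb_electrodes <- function(response_epochs, pools, n_top = 2L) {
  score_hemi <- function(pool, hemi) {
    crit <- t(vapply(pool, function(ch) {
      at_resp <- c(contra = NA, ipsi = NA)
      sums <- c(contra = 0, ipsi = 0); ns <- c(contra = 0, ipsi = 0)
      slopes <- numeric(0)
      for (e in response_epochs) {
        side <- e$trial$response_side
        lat <- if (contra_hemisphere(side) == hemi) "contra" else "ipsi"
        mb <- mu_beta_amplitude(stft_amplitude(e, channels = ch))
        a0 <- mb$amplitude[which.min(abs(mb$times_ms))]
        sums[lat] <- sums[lat] + a0
        ns[lat] <- ns[lat] + 1
        if (lat == "contra") {
          sel <- mb$times_ms >= -400 & mb$times_ms <= 0
          if (sum(sel) >= 2) {
            slopes <- c(slopes,
                        stats::coef(stats::lm(mb$amplitude[sel] ~
                                                mb$times_ms[sel]))[2])
          }
        }
      }
      d <- if (all(ns > 0)) sums["ipsi"] / ns["ipsi"] -
             sums["contra"] / ns["contra"] else 0
      c(amp_diff = unname(d),
        neg_slope = if (length(slopes)) -mean(slopes) * 1000 else 0)
    }, numeric(2)))
    rs <- rank(-crit[, "amp_diff"], ties.method = "first") +
      rank(-crit[, "neg_slope"], ties.method = "first")
    ord <- order(rs, seq_along(pool))
    data.frame(channel = pool, amp_diff = crit[, "amp_diff"],
               neg_slope = crit[, "neg_slope"], rank_sum = rs,
               stringsAsFactors = FALSE)[ord, ]
  }
  left <- score_hemi(pools$central_left, "left")
  right <- score_hemi(pools$central_right, "right")
  low_conf <- max(abs(c(left$amp_diff, right$amp_diff))) < 1e-8
  list(left = left$channel[seq_len(n_top)],
       right = right$channel[seq_len(n_top)],
       scores = list(left = left, right = right),
       low_confidence = low_conf)
}

#' Extract per-trial measures for the statistical battery
#'
#' Runs the spectral stage on preprocessed epochs and summarises each
#' trial into the analysis windows: marginal SSVEP during evidence
#' (680:975 ms post evidence onset, after the final pulse offset at
#' 650 ms) and during the baseline phase (-752:-214 ms, from cue-locked
#' epochs), pre-evidence mu-beta lateralisation (-752:-215 ms), alpha
#' amplitude (-410:-70 ms), and pre- (-200:-50 ms) / post-response
#' (50:200 ms) marginal SSVEP from response-locked epochs. Both printed
#' forms of the baseline window (-214 vs -215 ms) select the same STFT
#' midpoints because estimates live on the 50 ms grid.
#'
#' @param prep Output of [preprocess_trials()].
#' @param ssvep_channels,mb_channels,alpha_channels Selected electrode
#'   labels (`mb_channels` is `list(left =, right =)`).
#' @return A data frame, one row per evidence-locked trial, with the
#'   trial metadata and measure columns (NA where an epoch type was
#'   rejected).
#' @export
extract_trial_measures <- function(prep,
                                   ssvep_channels,
                                   mb_channels,
                                   alpha_channels) {
  uid_of <- function(e) as.character(e$trial$trial_uid %||%
                                       e$trial$trial_index)
  cue_by_uid <- stats::setNames(prep$cue, vapply(prep$cue, uid_of, ""))
  resp_by_uid <- stats::setNames(prep$response,
                                 vapply(prep$response, uid_of, ""))

  rows <- lapply(prep$evidence, function(e) {
    tr <- e$trial
    uid <- uid_of(e)
    f_tgt <- tr$target_tag_hz
    f_ntg <- setdiff(TAG_FREQS, f_tgt)
    spec_ev <- stft_amplitude(e, channels = ssvep_channels)
    marg_ev <- marginal_ssvep(ssvep_normalized(spec_ev, f_tgt),
                              ssvep_normalized(spec_ev, f_ntg))

    out <- data.frame(
      trial_uid = uid,
      subject_id = tr$subject_id %||% NA_character_,
      session_index = tr$session_index,
      trial_index = tr$trial_index,
      cue = as.character(tr$cue),
      target_tilt = as.character(tr$target_tilt),
      target_tag_hz = f_tgt,
      pulse_type = as.character(tr$pulse_type),
      marginal_contrast_pct = tr$marginal_contrast_pct,
      rt_s = (tr$rt_ms %||% NA_real_) / 1000,
      correct = tr$correct %||% NA,
      exposure_frac = tr$exposure_frac %||% NA_real_,
      marginal_ssvep_evidence = series_window_mean(marg_ev, 680, 975),
      ssvep_target_evidence = series_window_mean(
        ssvep_normalized(spec_ev, f_tgt), 680, 975),
      ssvep_nontarget_evidence = series_window_mean(
        ssvep_normalized(spec_ev, f_ntg), 680, 975),
      marginal_ssvep_baseline = NA_real_,
      mb_lateralization_baseline = NA_real_,
      alpha_pre = NA_real_,
      ssvep_pre_response = NA_real_,
      ssvep_post_response = NA_real_,
      stringsAsFactors = FALSE
    )

    ce <- cue_by_uid[[uid]]
    if (!is.null(ce)) {
      spec_cue <- stft_amplitude(ce, channels = ssvep_channels)
      # baseline marginal: cued minus uncued SSVEP on directional trials,
      # target minus non-target under a neutral cue
      cued_is_target <- out$cue != "invalid"
      f_cued <- if (cued_is_target) f_tgt else f_ntg
      f_uncued <- setdiff(TAG_FREQS, f_cued)
      marg_base <- marginal_ssvep(ssvep_normalized(spec_cue, f_cued),
                                  ssvep_normalized(spec_cue, f_uncued))
      out$marginal_ssvep_baseline <- series_window_mean(marg_base, -752, -214)

      ref_side <- if (out$cue == "valid") out$target_tilt
                  else if (out$cue == "invalid")
                    contra_hemisphere(out$target_tilt)
                  else out$target_tilt
      mb <- mu_beta(stft_amplitude(ce, channels = mb_channels$left),
                    stft_amplitude(ce, channels = mb_channels$right),
                    reference_side = ref_side)
      out$mb_lateralization_baseline <-
        series_window_mean(mb$mb_contra, -752, -215) -
        series_window_mean(mb$mb_ipsi, -752, -215)

      alpha <- alpha_band(stft_amplitude(ce, channels = alpha_channels,
                                         window_ms = ALPHA_WINDOW_MS))
      out$alpha_pre <- series_window_mean(alpha, -410, -70)
    }

    re <- resp_by_uid[[uid]]
    if (!is.null(re)) {
      spec_r <- stft_amplitude(re, channels = ssvep_channels)
      marg_r <- marginal_ssvep(ssvep_normalized(spec_r, f_tgt),
                               ssvep_normalized(spec_r, f_ntg))
      out$ssvep_pre_response <- series_window_mean(marg_r, -200, -50)
      out$ssvep_post_response <- series_window_mean(marg_r, 50, 200)
    }
    out
  })
  do.call(rbind, rows)
}

#' Write trial measures to CSV (long and wide)
#'
#' @param measures Output of [extract_trial_measures()].
#' @param path_wide,path_long Output CSV paths (`NULL` to skip one form).
#' @return Invisibly, the paths written.
#' @export
write_trial_measures <- function(measures, path_wide, path_long = NULL) {
  utils::write.csv(measures, path_wide, row.names = FALSE)
  if (!is.null(path_long)) {
    mcols <- c("marginal_ssvep_evidence", "ssvep_target_evidence",
               "ssvep_nontarget_evidence", "marginal_ssvep_baseline",
               "mb_lateralization_baseline", "alpha_pre",
               "ssvep_pre_response", "ssvep_post_response")
    long <- do.call(rbind, lapply(mcols, function(m)
      data.frame(trial_uid = measures$trial_uid, measure = m,
                 value = measures[[m]], stringsAsFactors = FALSE)))
    utils::write.csv(long, path_long, row.names = FALSE)
  }
  invisible(c(path_wide, path_long))
}
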