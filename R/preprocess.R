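# Preprocessing chain: detrend + zero-phase low-pass, robust bad-channel
# detection, spherical-spline interpolation, average reference, epoching
# with baseline correction, threshold artifact rejection, and the CSD
# transform. The pipeline order is fixed:
# detrend/filter -> bad channels -> interpolate -> average reference ->
# epoch/baseline -> reject -> CSD.

#' Preprocessing configuration
#'
#' @param lowpass_hz Low-pass cutoff (Hz, -6 dB).
#' @param filter_order FIR order (Hamming design, applied forward and
#'   backward for zero phase).
#' @param veog_reject_uv Rejection threshold on the absolute VEOG
#'   difference (uV).
#' @param scalp_reject_uv Rejection threshold on any scalp channel (uV).
#' @param bad_channel_z Robust z threshold on log channel variance
#'   (two-sided).
#' @param csd_spline_order Spline order m for interpolation and CSD.
#' @param csd_lambda Regularisation for the CSD spline fit.
#' @param baseline_windows Per-epoch-type baseline intervals, ms.
#' @param epoch_windows Per-epoch-type spans, ms (half-open, cue- and
#'   evidence-locked relative to evidence onset; response-locked relative
#'   to the response).
#' @return A list with class `preproc_config`.
#' @export
preproc_config <- function(lowpass_hz = 40, filter_order = 128L,
                           veog_reject_uv = 250, scalp_reject_uv = 100,
                           bad_channel_z = 3.5,
                           csd_spline_order = 4L, csd_lambda = 1e-5,
                           baseline_windows = list(
                             cue = c(-1400, -1200),
                             evidence = c(-600, -400)),
                           epoch_windows = list(
                             cue = c(-1700, 500),
                             evidence = c(-400, 2000),
                             response = c(-600, 400))) {
  stopifnot(lowpass_hz > 0, veog_reject_uv > 0, scalp_reject_uv > 0,
            bad_channel_z > 0)
  structure(
    list(lowpass_hz = lowpass_hz, filter_order = as.integer(filter_order),
         veog_reject_uv = veog_reject_uv,
         scalp_reject_uv = scalp_reject_uv,
         bad_channel_z = bad_channel_z,
         csd_spline_order = as.integer(csd_spline_order),
         csd_lambda = csd_lambda,
         baseline_windows = baseline_windows,
         epoch_windows = epoch_windows),
    class = "preproc_config"
  )
}

#' Detrend and low-pass filter an epoch
#'
#' Removes the per-channel linear trend, then applies a zero-phase FIR
#' low-pass (Hamming design, default -6 dB at 40 Hz) forward and backward.
#'
#' @param epoch An `eeg_epoch`.
#' @param cfg A [preproc_config()].
#' @return The filtered `eeg_epoch`.
#' @export
detrend_filter <- function(epoch, cfg = preproc_config()) {
  stopifnot(epoch$fs_hz == FS_HZ)
  X <- epoch$data
  n <- ncol(X)
  tt <- seq_len(n)
  # closed-form least-squares line removal per channel
  tc <- tt - mean(tt)
  denom <- sum(tc^2)
  slope <- (X %*% tc) / denom
  X <- X - rowMeans(X) - slope %*% t(tc)

  b <- signal::fir1(cfg$filter_order, cfg$lowpass_hz / (FS_HZ / 2),
                    type = "low", window = signal::hamming(cfg$filter_order + 1))
  for (ch in seq_len(nrow(X))) {
    X[ch, ] <- signal::filtfilt(signal::Ma(b), X[ch, ])
  }
  epoch$data <- X
  epoch
}

#' Detect bad channels by robust variance analysis
#'
#' Computes, per scalp channel, the median across epochs of the log
#' per-epoch variance (so a single artifactual epoch cannot condemn a
#' channel) and flags channels whose robust z score (median/MAD across
#' channels) exceeds the threshold in either direction, catching both
#' persistently noisy and dead (flat) channels. Zero-variance channels
#' are always flagged.
#'
#' @param epochs A list of `eeg_epoch`s (or one epoch).
#' @param cfg A [preproc_config()].
#' @return Character vector of flagged channel labels. Warns when more
#'   than 20% of scalp channels are flagged.
#' @export
detect_bad_channels <- function(epochs, cfg = preproc_config()) {
  if (inherits(epochs, "eeg_epoch")) epochs <- list(epochs)
  mont <- epochs[[1]]$montage
  scalp <- which(mont$is_scalp)
  if (length(scalp) < 8L) stop("need at least 8 scalp channels")
  v <- apply(vapply(epochs, function(e)
    apply(e$data[scalp, , drop = FALSE], 1, stats::var),
    numeric(length(scalp))), 1, stats::median)
  flat <- v < 1e-12
  lv <- log(pmax(v, 1e-12))
  med <- stats::median(lv[!flat])
  madv <- stats::mad(lv[!flat])
  z <- if (madv > 0) (lv - med) / madv else rep(0, length(lv))
  bad <- flat | abs(z) > cfg$bad_channel_z
  labels <- mont$label[scalp][bad]
  if (length(labels) > 0.2 * length(scalp)) {
    warning("more than 20% of scalp channels flagged as bad")
  }
  labels
}

#' Interpolate bad channels with spherical splines
#'
#' Replaces each flagged scalp channel with its spherical-spline estimate
#' from the remaining scalp channels (spline order `csd_spline_order`,
#' interpolation uses a near-zero ridge for numerical stability).
#'
#' @param epoch An `eeg_epoch`.
#' @param bad Character vector of channel labels to rebuild (empty ->
#'   identity).
#' @param cfg A [preproc_config()].
#' @return The `eeg_epoch` with interpolated channels.
#' @export
interpolate_channels <- function(epoch, bad, cfg = preproc_config()) {
  if (length(bad) == 0L) return(epoch)
  mont <- epoch$montage
  scalp_labels <- mont$label[mont$is_scalp]
  stopifnot(all(bad %in% scalp_labels))
  good <- setdiff(scalp_labels, bad)
  if (length(bad) > 0.5 * length(scalp_labels)) {
    stop("more than half of the scalp channels are bad; refusing to ",
         "interpolate")
  }
  G <- spline_gh(cosine_angles(scalp_xyz(mont, good)),
                 m = cfg$csd_spline_order)$g
  Ggb <- spline_gh(cosine_angles(scalp_xyz(mont, bad),
                                 scalp_xyz(mont, good)),
                   m = cfg$csd_spline_order)$g
  fit <- spline_fit(G, epoch$data[match(good, mont$label), , drop = FALSE],
                    lambda = 1e-8)
  est <- Ggb %*% fit$C + matrix(fit$d, nrow = length(bad),
                                ncol = ncol(epoch$data), byrow = TRUE)
  epoch$data[match(bad, mont$label), ] <- est
  epoch
}

#' Re-reference to the scalp average
#'
#' Subtracts the instantaneous mean over scalp channels from every scalp
#' channel; VEOG channels are untouched. Idempotent, and channel
#' differences are unchanged.
#'
#' @param epoch An `eeg_epoch`.
#' @return The re-referenced `eeg_epoch`.
#' @export
rereference_average <- function(epoch) {
  scalp <- which(epoch$montage$is_scalp)
  mu <- colMeans(epoch$data[scalp, , drop = FALSE])
  epoch$data[scalp, ] <- sweep(epoch$data[scalp, , drop = FALSE], 2, mu)
  epoch
}

# Cut a half-open window [start, end) ms around an event from a continuous
# epoch; returns NULL (with a message in the log) when the window exits
# the recording.
cut_window <- function(epoch, event_ms, start_ms, end_ms, alignment) {
  if (is.null(event_ms) || is.na(event_ms)) return(NULL)
  dt <- 1000 / FS_HZ
  t_rel <- epoch$t_ms - event_ms
  keep <- t_rel >= start_ms & t_rel < end_ms
  if (!any(keep)) return(NULL)
  # event too near the recording edge -> incomplete epoch: require a sample
  # within one sample period of each window edge
  if (t_rel[1] >= start_ms + dt || t_rel[length(t_rel)] < end_ms - dt) {
    return(NULL)
  }
  out <- epoch
  out$data <- epoch$data[, keep, drop = FALSE]
  out$t_ms <- t_rel[keep]
  out$t0_ms <- out$t_ms[1]
  out$alignment <- alignment
  out
}

#' Segment a continuous trial into epochs with baseline correction
#'
#' Cuts the three epoch types from continuous per-trial data: cue-locked
#' (-1700:500 ms) and evidence-locked (-400:2000 ms), both relative to
#' evidence onset, and later response-locked (-600:400 ms relative to the
#' response; see [response_locked_epoch()], cut from evidence-locked data
#' after artifact rejection). Baseline correction subtracts the
#' per-channel mean over the configured window (cue-locked -1400:-1200 ms;
#' evidence-locked -600:-400 ms, both relative to evidence onset); the
#' baseline mean is computed from the continuous data, so windows outside
#' the cut span are honoured. All windows are half-open `[start, end)`.
#'
#' @param epoch A continuous `eeg_epoch` whose `t_ms` axis is relative to
#'   evidence onset.
#' @param cfg A [preproc_config()].
#' @return A list with `cue` and `evidence` epochs (`NULL` with a log
#'   entry if the window exits the recording) and a `log` character
#'   vector.
#' @export
epoch_and_baseline <- function(epoch, cfg = preproc_config()) {
  log <- character(0)
  out <- list()
  for (type in c("cue", "evidence")) {
    w <- cfg$epoch_windows[[type]]
    e <- cut_window(epoch, 0, w[1], w[2], type)
    if (is.null(e)) {
      log <- c(log, sprintf("%s: dropped (window [%g,%g) exits recording)",
                            type, w[1], w[2]))
      out[[type]] <- NULL
      next
    }
    bw <- cfg$baseline_windows[[type]]
    bidx <- epoch$t_ms >= bw[1] & epoch$t_ms < bw[2]
    base <- rowMeans(epoch$data[, bidx, drop = FALSE])
    e$data <- e$data - base
    e$baseline_window_ms <- bw
    out[[type]] <- e
  }
  out$log <- log
  out
}

#' Cut a response-locked epoch from evidence-locked data
#'
#' @param evidence_epoch An evidence-locked `eeg_epoch` (times relative to
#'   evidence onset).
#' @param rt_ms Response time (ms after evidence onset).
#' @param cfg A [preproc_config()].
#' @return A response-locked `eeg_epoch` (times relative to the response),
#'   or `NULL` when the window exits the epoch.
#' @export
response_locked_epoch <- function(evidence_epoch, rt_ms,
                                  cfg = preproc_config()) {
  w <- cfg$epoch_windows$response
  cut_window(evidence_epoch, rt_ms, w[1], w[2], "response")
}

#' Threshold artifact rejection
#'
#' A trial is excluded when the absolute difference between the two VEOG
#' channels exceeds `veog_reject_uv` (250 uV) at any sample, or when any
#' scalp channel exceeds `scalp_reject_uv` (100 uV) in absolute value at
#' any sample. Rejection is run separately per epoch type, so cue- and
#' evidence-locked analyses have independent keep-sets.
#'
#' @param epochs List of `eeg_epoch`s of one epoch type.
#' @param cfg A [preproc_config()].
#' @return A list: `kept` (the surviving epochs), `kept_idx`, and `log`
#'   (data frame `trial_uid`, `reason`).
#' @export
reject_artifacts <- function(epochs, cfg = preproc_config()) {
  mont <- epochs[[1]]$montage
  iu <- which(mont$label == "VEOGupper")
  il <- which(mont$label == "VEOGlower")
  if (length(iu) != 1L || length(il) != 1L) stop("VEOG pair not found")
  scalp <- which(mont$is_scalp)
  reasons <- vapply(epochs, function(e) {
    if (max(abs(e$data[iu, ] - e$data[il, ])) > cfg$veog_reject_uv) {
      "veog"
    } else if (max(abs(e$data[scalp, ])) > cfg$scalp_reject_uv) {
      "scalp"
    } else ""
  }, character(1))
  uid <- vapply(epochs, function(e)
    if (!is.null(e$trial$trial_uid)) as.character(e$trial$trial_uid)
    else as.character(e$trial$trial_index %||% NA), character(1))
  keep <- reasons == ""
  list(kept = epochs[keep], kept_idx = which(keep),
       log = data.frame(trial_uid = uid[!keep], reason = reasons[!keep],
                        stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Current source density transform
#'
#' Estimates the surface Laplacian of the scalp potential with spherical
#' splines (order m, regularisation lambda), sharpening topographies and
#' reducing volume conduction. Output units are uV/m^2 on the unit
#' sphere. The transform is linear and maps spatially uniform fields to
#' zero. VEOG channels pass through unchanged.
#'
#' @param epoch An `eeg_epoch`.
#' @param cfg A [preproc_config()].
#' @return The CSD-transformed `eeg_epoch`.
#' @export
csd_transform <- function(epoch, cfg = preproc_config()) {
  mont <- epoch$montage
  if (any(!is.finite(as.matrix(mont[mont$is_scalp, c("x", "y", "z")])))) {
    stop("montage positions missing; CSD requires unit-sphere coordinates")
  }
  scalp <- which(mont$is_scalp)
  gh <- spline_gh(cosine_angles(scalp_xyz(mont)), m = cfg$csd_spline_order)
  fit <- spline_fit(gh$g, epoch$data[scalp, , drop = FALSE],
                    lambda = cfg$csd_lambda)
  epoch$data[scalp, ] <- gh$h %*% fit$C
  epoch$units <- "uV/m^2"
  epoch
}

#' Run the full preprocessing chain on a set of continuous trials
#'
#' Fixed order: detrend/filter, bad-channel detection (across all trials)
#' and interpolation, average reference, epoching with baseline
#' correction, threshold artifact rejection (separately for cue- and
#' evidence-locked epochs), CSD, and response-locked cutting from the
#' surviving evidence-locked epochs.
#'
#' @param trials List of continuous `eeg_epoch`s (one per trial, times
#'   relative to evidence onset; `trial$rt_ms` places the response).
#' @param cfg A [preproc_config()].
#' @param csd Apply the CSD transform (default TRUE).
#' @return A list: `cue`, `evidence`, `response` (lists of clean epochs),
#'   `bad_channels`, `rejection_log`, `log`.
#' @export
preprocess_trials <- function(trials, cfg = preproc_config(), csd = TRUE) {
  filtered <- lapply(trials, detrend_filter, cfg = cfg)
  bad <- detect_bad_channels(filtered, cfg)
  if (length(bad) > 0) {
    filtered <- lapply(filtered, interpolate_channels, bad = bad, cfg = cfg)
  }
  filtered <- lapply(filtered, rereference_average)

  cues <- list(); evs <- list(); log <- character(0)
  for (e in filtered) {
    seg <- epoch_and_baseline(e, cfg)
    log <- c(log, seg$log)
    if (!is.null(seg$cue)) cues[[length(cues) + 1L]] <- seg$cue
    if (!is.null(seg$evidence)) evs[[length(evs) + 1L]] <- seg$evidence
  }
  rej_cue <- reject_artifacts(cues, cfg)
  rej_ev <- reject_artifacts(evs, cfg)
  tag_log <- function(lg, type) {
    lg$epoch_type <- rep(type, nrow(lg))
    lg
  }
  rejection_log <- rbind(tag_log(rej_cue$log, "cue"),
                         tag_log(rej_ev$log, "evidence"))

  post <- function(es) if (csd) lapply(es, csd_transform, cfg = cfg) else es
  cue_clean <- post(rej_cue$kept)
  ev_clean <- post(rej_ev$kept)
  resp <- list()
  for (e in ev_clean) {
    rl <- response_locked_epoch(e, e$trial$rt_ms %||% NA, cfg)
    if (!is.null(rl)) resp[[length(resp) + 1L]] <- rl
  }
  list(cue = cue_clean, evidence = ev_clean, response = resp,
       bad_channels = bad, rejection_log = rejection_log, log = log)
}
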