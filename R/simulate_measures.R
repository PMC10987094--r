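# Trial-level generator for the statistical battery: draws per-trial
# measure rows (marginal SSVEP, mu-beta lateralisation, alpha, behaviour)
# directly from the forward model's summary distribution, with subject
# random intercepts. The full EEG forward model (simulate_trial_eeg) is
# exercised end to end at small n elsewhere; this generator provides the
# replicate counts needed for power and type-I calibration studies at
# desk scale.

#' Effect parameters for the measures-level generator
#'
#' All measure scales are in the units of the extracted amplitudes
#' (uV/m^2 after CSD). `cue_evidence_gain` multiplies the mean marginal
#' SSVEP per cue condition; with `cue_gain_exposure_ramp = TRUE` the gain
#' moves linearly from 1 at the start of testing to its nominal value at
#' the end (the emergent-with-exposure pattern). `ssvep_accuracy_beta`
#' and `ssvep_rt_beta_s` couple the single-trial marginal SSVEP to
#' behaviour (logit shift per unit amplitude; seconds per unit
#' amplitude).
#'
#' @param target_mean,nontarget_mean Mean single-grating amplitudes (the
#'   mean neutral-trial marginal SSVEP is their difference).
#' @param cue_evidence_gain Named gain by cue (`valid`, `invalid`,
#'   `neutral`).
#' @param cue_gain_exposure_ramp Ramp the gain with exposure?
#' @param mb_lateralization Mean extra (more negative) contralateral-
#'   minus-ipsilateral mu-beta on cued vs neutral trials.
#' @param alpha_neutral_drop Reduction of mean alpha amplitude on neutral
#'   trials (greater desynchronisation).
#' @param alpha_mean Mean alpha amplitude on cued trials.
#' @param subject_sd Random-intercept SD of the single-grating SSVEP
#'   level (shared by target and non-target).
#' @param subject_sd_marginal Random-intercept SD of the marginal SSVEP
#'   (a per-subject differential-encoding offset that does not cancel in
#'   target minus non-target).
#' @param subject_sd_rt_s,subject_sd_acc Random-intercept SDs of the
#'   behavioural responses (seconds; logit units).
#' @param noise_sd Residual SD of the SSVEP measures.
#' @param mb_noise_sd,alpha_noise_sd Residual SDs.
#' @param ssvep_accuracy_beta,ssvep_rt_beta_s Single-trial SSVEP to
#'   behaviour couplings (0 = no link).
#' @param behav Overrides passed to [simulate_behaviour()] as
#'   `behav_params`.
#' @return A list with class `measures_params`.
#' @export
measures_params <- function(target_mean = 2.5, nontarget_mean = 1.5,
                            cue_evidence_gain = c(valid = 1, invalid = 1,
                                                  neutral = 1),
                            cue_gain_exposure_ramp = FALSE,
                            mb_lateralization = 0,
                            alpha_neutral_drop = 0,
                            alpha_mean = 3,
                            subject_sd = 0.3,
                            subject_sd_marginal = 0.15,
                            subject_sd_rt_s = 0.05,
                            subject_sd_acc = 0.15,
                            noise_sd = 0.8,
                            mb_noise_sd = 0.8,
                            alpha_noise_sd = 0.8,
                            ssvep_accuracy_beta = 0,
                            ssvep_rt_beta_s = 0,
                            behav = list()) {
  structure(as.list(environment()), class = "measures_params")
}

#' Simulate an analysis table of per-trial measures
#'
#' Draws a trial table from [generate_session()] per subject, then
#' simulates the analysis-window measures with subject random intercepts
#' and the configured cue effects, and behaviour via
#' [simulate_behaviour()] (optionally coupled to the trial's marginal
#' SSVEP).
#'
#' @param n_subjects,trials_per_subject Size of the simulated study.
#' @param params A [measures_params()].
#' @param seed Integer seed.
#' @return A data frame ready for [build_analysis_table()].
#' @export
simulate_measures_table <- function(n_subjects = 8,
                                    trials_per_subject = 64,
                                    params = measures_params(),
                                    seed = 1L) {
  p <- params
  out <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    sched <- generate_session(trials_per_subject,
                              seed = sub_seed(seed, s),
                              session_index = 1L)
    n <- nrow(sched)
    local_rng(sub_seed(seed, 7000L + s))
    b_subj <- stats::rnorm(1, 0, p$subject_sd)
    b_marg <- stats::rnorm(1, 0, p$subject_sd_marginal)
    b_rt <- stats::rnorm(1, 0, p$subject_sd_rt_s)
    b_acc <- stats::rnorm(1, 0, p$subject_sd_acc)
    b_resp <- stats::rnorm(1, 0, p$subject_sd_marginal)
    exposure <- (seq_len(n) - 1) / max(1, n - 1)

    gain <- p$cue_evidence_gain[as.character(sched$cue)]
    if (isTRUE(p$cue_gain_exposure_ramp)) {
      gain <- 1 + (gain - 1) * exposure
    }
    # marginal = target - nontarget by construction; the cue gain scales
    # the differential around the grand-mean amplitude
    half_eff <- (p$target_mean - p$nontarget_mean) / 2 * gain
    centre <- (p$target_mean + p$nontarget_mean) / 2
    tgt <- centre + half_eff + b_subj + b_marg / 2 +
      stats::rnorm(n, 0, p$noise_sd / sqrt(2))
    ntg <- centre - half_eff + b_subj - b_marg / 2 +
      stats::rnorm(n, 0, p$noise_sd / sqrt(2))
    marg <- tgt - ntg
    marg_mean <- p$target_mean - p$nontarget_mean

    cued <- sched$cue != "neutral"
    mb <- -p$mb_lateralization * cued + b_subj * 0.5 +
      stats::rnorm(n, 0, p$mb_noise_sd)
    alpha <- p$alpha_mean - p$alpha_neutral_drop * (!cued) + b_subj +
      stats::rnorm(n, 0, p$alpha_noise_sd)

    # behaviour: same model as simulate_behaviour(), drawn vectorised
    bp <- utils::modifyList(list(
      base_p_correct = 0.70,
      acc_logit_shift = c(valid = 0.184, invalid = -0.219, neutral = 0),
      rt_shift_s = c(correct_valid = -0.043, correct_invalid = 0.085,
                     error_valid = 0.084, error_invalid = -0.047,
                     correct_neutral = 0, error_neutral = 0),
      rt_meanlog = log(0.65) - 0.35^2 / 2,
      rt_sdlog = 0.35,
      rt_shift_floor_s = 0.25
    ), p$behav)
    logit_p <- stats::qlogis(bp$base_p_correct) + b_acc +
      bp$acc_logit_shift[as.character(sched$cue)] +
      p$ssvep_accuracy_beta * (marg - marg_mean)
    correct <- stats::runif(n) < stats::plogis(logit_p)
    key <- paste0(ifelse(correct, "correct_", "error_"),
                  as.character(sched$cue))
    rt <- bp$rt_shift_floor_s +
      stats::rlnorm(n, bp$rt_meanlog, bp$rt_sdlog) +
      bp$rt_shift_s[key] + b_rt +
      p$ssvep_rt_beta_s * (marg - marg_mean)
    rt <- pmax(rt, 0.15)

    out[[s]] <- data.frame(
      trial_uid = sprintf("S%02d_%04d", s, sched$trial_index),
      subject_id = sprintf("S%02d", s),
      session_index = sched$session_index,
      trial_index = sched$trial_index,
      cue = as.character(sched$cue),
      target_tilt = sched$target_tilt,
      target_tag_hz = sched$target_tag_hz,
      pulse_type = sched$pulse_type,
      marginal_contrast_pct = sched$marginal_contrast_pct,
      exposure_frac = exposure,
      rt_s = rt,
      correct = correct,
      marginal_ssvep_evidence = marg,
      ssvep_target_evidence = tgt,
      ssvep_nontarget_evidence = ntg,
      marginal_ssvep_baseline = b_subj + stats::rnorm(n, 0, p$noise_sd),
      mb_lateralization_baseline = mb,
      alpha_pre = alpha,
      ssvep_pre_response = marg + stats::rnorm(n, 0, p$noise_sd / 2),
      ssvep_post_response = marg + b_resp +
        stats::rnorm(n, 0, p$noise_sd / 2),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}
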