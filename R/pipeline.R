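# End-to-end orchestration: simulate -> preprocess -> extract -> analyse,
# with a structured config, a manifest, and deterministic re-runs.

#' Pipeline run configuration
#'
#' @param seed Base seed for every stochastic stage.
#' @param scale Preset: `"smoke"` (2 subjects x 32 trials, completes in
#'   well under two minutes on one CPU), `"desk"` (4 subjects x 64
#'   trials), or `"study_scale"` (12 subjects x 384 trials; slow).
#' @param out_dir Run directory.
#' @param gen A [gen_params()].
#' @param preproc A [preproc_config()].
#' @param behav `behav_params` for [simulate_behaviour()].
#' @param csd Apply the CSD transform in preprocessing.
#' @param n_neighbours Neighbour bins per side for SSVEP normalisation.
#' @param registry Analysis registry path.
#' @param overrides Named list applied over the preset fields
#'   (`n_subjects`, `trials_per_subject`, ...).
#' @return A list with class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       scale = c("smoke", "desk", "study_scale"),
                       out_dir = tempfile("ssvepcue_run_"),
                       gen = NULL,
                       preproc = preproc_config(),
                       behav = list(),
                       csd = TRUE,
                       n_neighbours = 2L,
                       registry = system.file("analyses.yaml",
                                              package = "ssvepcue"),
                       overrides = list()) {
  scale <- match.arg(scale)
  size <- switch(scale,
    smoke = list(n_subjects = 2L, trials_per_subject = 32L),
    desk = list(n_subjects = 4L, trials_per_subject = 64L),
    study_scale = list(n_subjects = 12L, trials_per_subject = 384L))
  if (is.null(gen)) gen <- gen_params(seed = seed)
  cfg <- utils::modifyList(
    c(size,
      list(seed = as.integer(seed), scale = scale, out_dir = out_dir,
           gen = gen, preproc = preproc, behav = behav, csd = csd,
           n_neighbours = as.integer(n_neighbours), registry = registry)),
    overrides)
  class(cfg) <- "run_config"
  cfg
}

#' Run the full pipeline
#'
#' Simulates a dataset (trial schedules, behaviour, EEG), preprocesses
#' every trial, selects electrodes from the candidate pools, extracts the
#' per-trial measures, runs the registered analysis battery, and writes
#' all stage outputs plus a manifest (config echo, seed, stage sizes) to
#' the run directory. Re-running with the same config reproduces
#' identical trial tables and measures.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list: `out_dir`, `measures`, `battery`,
#'   `electrodes`, `prep_summary`.
#' @export
run_pipeline <- function(cfg = run_config()) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage_dir <- function(x) {
    d <- file.path(cfg$out_dir, x)
    dir.create(d, showWarnings = FALSE)
    d
  }

  data_dir <- stage_dir("data")
  make_dataset(n_subjects = cfg$n_subjects, sessions_per_subject = 1,
               trials_per_session = cfg$trials_per_subject,
               params = cfg$gen, behav_params = cfg$behav,
               seed = cfg$seed, dir = data_dir)

  pools <- electrode_pools(cfg$gen$montage)
  all_measures <- list()
  prep_summary <- list()
  sel <- NULL
  trial_files <- sort(list.files(data_dir, "_trials\\.csv$",
                                 full.names = TRUE))
  for (tf in trial_files) {
    epochs <- readRDS(sub("_trials\\.csv$", "_epochs.rds", tf))
    prep <- preprocess_trials(epochs, cfg$preproc, csd = cfg$csd)
    prep_summary[[tf]] <- list(
      n_in = length(epochs),
      n_cue = length(prep$cue), n_evidence = length(prep$evidence),
      n_response = length(prep$response),
      bad_channels = prep$bad_channels,
      n_rejected = nrow(prep$rejection_log))
    if (is.null(sel)) {
      sel <- list(
        ssvep = select_ssvep_electrodes(prep$evidence,
                                        pools$occipital)$channels,
        mb = {
          mbsel <- select_mb_electrodes(prep$response, pools)
          list(left = mbsel$left, right = mbsel$right)
        },
        alpha = pools$alpha_midline)
    }
    m <- extract_trial_measures(prep, ssvep_channels = sel$ssvep,
                                mb_channels = sel$mb,
                                alpha_channels = sel$alpha)
    all_measures[[tf]] <- m
  }
  measures <- do.call(rbind, all_measures)
  rownames(measures) <- NULL
  res_dir <- stage_dir("results")
  write_trial_measures(measures, file.path(res_dir, "measures.csv"),
                       file.path(res_dir, "measures_long.csv"))

  table <- build_analysis_table(measures)
  battery <- run_analysis_battery(table, registry = cfg$registry)
  write_effect_tables(battery$results,
                      file.path(res_dir, "effect_tables.csv"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("ssvepcue")),
    seed = cfg$seed, scale = cfg$scale,
    n_subjects = cfg$n_subjects,
    trials_per_subject = cfg$trials_per_subject,
    csd = cfg$csd, n_neighbours = cfg$n_neighbours,
    electrodes = sel,
    defaults_used = list(
      stft_window_ms = SSVEP_WINDOW_MS, alpha_window_ms = ALPHA_WINDOW_MS,
      stft_step_ms = STFT_STEP_MS,
      lowpass_hz = cfg$preproc$lowpass_hz,
      bad_channel_z = cfg$preproc$bad_channel_z,
      veog_reject_uv = cfg$preproc$veog_reject_uv,
      scalp_reject_uv = cfg$preproc$scalp_reject_uv,
      csd_spline_order = cfg$preproc$csd_spline_order,
      csd_lambda = cfg$preproc$csd_lambda),
    prep_summary = prep_summary)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(list(out_dir = cfg$out_dir, measures = measures,
                 battery = battery, electrodes = sel,
                 prep_summary = prep_summary))
}

#' Build a small golden fixture dataset
#'
#' A deterministic, committed-size dataset for tests: all 16 pulse cells,
#' constructed epochs that exercise both artifact-rejection reasons
#' (a VEOG blink above 250 uV and a scalp excursion above 100 uV), and a
#' ground-truth manifest. Regenerates byte-identically from the seed.
#'
#' @param seed Integer seed.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
make_fixtures <- function(seed = 1L, dir = tempfile("ssvepcue_fixture_")) {
  params <- gen_params(blink_rate_hz = 0, seed = seed)
  make_dataset(n_subjects = 1, sessions_per_subject = 1,
               trials_per_session = 16, params = params,
               seed = seed, dir = dir)
  # append two constructed artifact trials to the epoch container
  base <- file.path(dir, "S01_ses01")
  epochs <- readRDS(paste0(base, "_epochs.rds"))
  blinky <- epochs[[1]]
  iu <- which(blinky$montage$label == "VEOGupper")
  blinky$data[iu, 100:160] <- blinky$data[iu, 100:160] + 400
  blinky$trial$trial_uid <- "S01_01_artifact_veog"
  # smooth 200 ms excursion on a quiet channel inside the evidence epoch,
  # low-frequency enough to survive the 40 Hz low-pass and small enough in
  # variance not to trip the bad-channel detector
  spiky <- epochs[[2]]
  p7 <- which(spiky$montage$label == "P7")
  bump <- 180 * 0.5 * (1 - cos(2 * pi * seq_len(103) / 103))
  spiky$data[p7, 1100:1202] <- spiky$data[p7, 1100:1202] + bump
  spiky$trial$trial_uid <- "S01_01_artifact_scalp"
  epochs <- c(epochs, list(blinky, spiky))
  saveRDS(epochs, paste0(base, "_epochs.rds"))
  invisible(dir)
}
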