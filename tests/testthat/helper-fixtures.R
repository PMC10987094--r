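# Shared test fixtures, built once per test run.

fs_hz <- 512

# deterministic RNG closure for simulated observers
seeded_responder <- function(seed, p_fun) {
  env <- new.env()
  set.seed(seed)
  env$state <- .Random.seed
  function(level) {
    assign(".Random.seed", env$state, globalenv())
    r <- stats::runif(1) < p_fun(level)
    env$state <- get(".Random.seed", globalenv())
    r
  }
}

# epoch with arbitrary channel data on the default montage
make_epoch <- function(data, t_ms = (seq_len(ncol(data)) - 1) * 1000 / fs_hz,
                       alignment = "evidence", trial = NULL) {
  m <- default_montage()
  eeg_epoch(data, t_ms, m, alignment = alignment, trial = trial)
}

# multichannel epoch holding the same single-channel signal everywhere
uniform_epoch <- function(x, ...) {
  make_epoch(matrix(rep(x, each = 37), 37, length(x)), ...)
}

# evidence-locked-sized time axis (about -400:2000 ms)
evidence_time_ms <- function() {
  k <- seq(ceiling(-400 * fs_hz / 1000), ceiling(2000 * fs_hz / 1000) - 1L)
  k * 1000 / fs_hz
}

# naive DFT amplitude oracle: loop over frequencies, no FFT
dft_amplitude_oracle <- function(x, freqs_hz, fs = fs_hz) {
  n <- length(x)
  vapply(seq_along(freqs_hz), function(k) {
    f <- freqs_hz[k]
    re <- sum(x * cos(2 * pi * f * (seq_len(n) - 1) / fs))
    im <- sum(x * sin(2 * pi * f * (seq_len(n) - 1) / fs))
    a <- 2 * sqrt(re^2 + im^2) / n
    if (k == 1L && f == 0) a / 2 else a
  }, numeric(1))
}

# one small preprocessed dataset shared by the spectral/pipeline tests
shared <- new.env()
shared_prep <- function() {
  if (is.null(shared$prep)) {
    sched <- generate_session(16, seed = 101)
    sched$subject_id <- "S01"
    sched$trial_uid <- sprintf("S01_%04d", sched$trial_index)
    params <- gen_params(blink_rate_hz = 0, seed = 101)
    trials <- lapply(seq_len(nrow(sched)), function(i) {
      tr <- sched[i, ]
      simulate_trial_eeg(tr, contrast_timecourse(tr), params)
    })
    shared$sched <- sched
    shared$prep <- suppressWarnings(preprocess_trials(trials))
  }
  shared$prep
}
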