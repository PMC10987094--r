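test_that("STFT amplitudes equal a direct DFT oracle and scale on-bin sinusoids to 1", {
  t_ms <- evidence_time_ms()
  t_s <- t_ms / 1000
  n_win <- 205
  f_bin <- fs_hz / n_win * 10          # an exact bin near 25 Hz
  x <- 2 * sin(2 * pi * f_bin * t_s) + 0.5 * sin(2 * pi * 30.2 * t_s)
  e <- uniform_epoch(x, t_ms = t_ms)
  spec <- stft_amplitude(e, channels = "Oz")

  expect_equal(spec$n_window_samples, n_win)
  expect_equal(diff(spec$freqs_hz)[1], fs_hz / n_win, tolerance = 1e-12)
  expect_true(all(diff(spec$times_ms) == 50))
  expect_true(all(spec$amplitude >= 0))

  # oracle comparison on several windows
  half <- n_win * (1000 / fs_hz) / 2
  for (w in c(1, 8, 20)) {
    mid <- spec$times_ms[w]
    i0 <- which(t_ms >= mid - half - 1e-9)[1]
    seg <- x[i0:(i0 + n_win - 1)]
    oracle <- dft_amplitude_oracle(seg, spec$freqs_hz)
    expect_lt(max(abs(spec$amplitude[w, ] - oracle)), 1e-6)
  }

  # an on-bin sinusoid alone reads its amplitude exactly at its bin
  pure <- stft_amplitude(uniform_epoch(2 * sin(2 * pi * f_bin * t_s),
                                       t_ms = t_ms), channels = "Oz")
  k <- which.min(abs(pure$freqs_hz - f_bin))
  expect_equal(unname(pure$amplitude[5, k]), 2, tolerance = 1e-9)

  # zero signal: all bins zero
  z <- stft_amplitude(uniform_epoch(numeric(length(t_ms)), t_ms = t_ms),
                      channels = "Oz")
  expect_true(all(z$amplitude == 0))

  # window resolutions: 400 ms -> ~2.5 Hz, 360 ms -> ~2.78 Hz
  spec360 <- stft_amplitude(e, channels = "Oz", window_ms = 360)
  expect_equal(diff(spec360$freqs_hz)[1], fs_hz / round(0.36 * fs_hz),
               tolerance = 1e-12)
  expect_equal(diff(spec$freqs_hz)[1], 2.5, tolerance = 0.01)
  expect_equal(diff(spec360$freqs_hz)[1], 1000 / 360, tolerance = 0.02)

  # a window longer than the epoch is an error
  short <- uniform_epoch(x[1:100], t_ms = t_ms[1:100])
  expect_error(stft_amplitude(short, channels = "Oz"), "window_ms")
})

test_that("spectral energy never exceeds time-domain energy (rectangular taper)", {
  set.seed(23)
  t_ms <- evidence_time_ms()
  x <- rnorm(length(t_ms))
  e <- uniform_epoch(x, t_ms = t_ms)
  spec <- stft_amplitude(e, channels = "Oz")
  n_win <- spec$n_window_samples
  half <- n_win * (1000 / fs_hz) / 2
  for (w in c(2, 10)) {
    i0 <- which(t_ms >= spec$times_ms[w] - half - 1e-9)[1]
    seg <- x[i0:(i0 + n_win - 1)]
    a <- spec$amplitude[w, ]
    # one-sided amplitudes back to total energy
    en_spec <- n_win * (a[1]^2 + sum((a[-1] / 2)^2 * 2))
    expect_lte(en_spec, sum(seg^2) + 1e-6)
  }
})

test_that("each STFT estimate uses only samples inside its half-open window", {
  t_ms <- evidence_time_ms()
  n_win <- 205
  half <- n_win * (1000 / fs_hz) / 2
  # an impulse just outside the window of one midpoint must not leak in
  x <- numeric(length(t_ms))
  mid <- 500
  edge_idx <- which(t_ms >= mid - half - 1e-9)[1] - 1L   # last sample before
  x[edge_idx] <- 100
  spec <- stft_amplitude(uniform_epoch(x, t_ms = t_ms), channels = "Oz")
  w <- which(spec$times_ms == mid)
  expect_true(all(spec$amplitude[w, ] == 0))
  # but it does appear in the previous window
  expect_gt(max(spec$amplitude[w - 1L, ]), 0)
})

test_that("neighbour-bin normalisation recovers tags and stays unbiased on white noise", {
  t_ms <- evidence_time_ms()
  t_s <- t_ms / 1000
  # injected 20 and 25 Hz components recovered independently (noise-free)
  x <- 3 * sin(2 * pi * 20 * t_s) + 1.5 * sin(2 * pi * 25 * t_s)
  spec <- stft_amplitude(uniform_epoch(x, t_ms = t_ms), channels = "Oz")
  a20 <- mean(ssvep_normalized(spec, 20)$amplitude)
  a25 <- mean(ssvep_normalized(spec, 25)$amplitude)
  expect_equal(a20, 3, tolerance = 0.02)
  expect_equal(a25, 1.5, tolerance = 0.02)

  # white noise: mean normalised amplitude within 3 SE of zero
  set.seed(29)
  vals <- replicate(400, {
    xn <- rnorm(820)
    sp <- stft_amplitude(uniform_epoch(xn, t_ms = t_ms[1:820]),
                         channels = "Oz")
    mean(ssvep_normalized(sp, 20)$amplitude)
  })
  expect_lt(abs(mean(vals)), 3 * sd(vals) / sqrt(length(vals)))

  # neighbour range must stay inside the spectrum
  expect_error(ssvep_normalized(spec, 2.5, n_neighbours = 5), "exits")
})

test_that("the marginal SSVEP is an exact antisymmetric difference", {
  t_ms <- evidence_time_ms()
  set.seed(31)
  x <- rnorm(length(t_ms))
  spec <- stft_amplitude(uniform_epoch(x, t_ms = t_ms), channels = "Oz")
  s20 <- ssvep_normalized(spec, 20)
  s25 <- ssvep_normalized(spec, 25)
  m1 <- marginal_ssvep(s20, s25)
  m2 <- marginal_ssvep(s25, s20)
  expect_equal(m1$amplitude, -m2$amplitude, tolerance = 1e-12)
  zero <- marginal_ssvep(s20, s20)
  expect_true(all(zero$amplitude == 0))
  bad <- s25
  bad$times_ms <- bad$times_ms + 50
  expect_error(marginal_ssvep(s20, bad), "misaligned")
})

test_that("mu-beta excludes the tag bins and maps hemispheres to contra/ipsi", {
  t_ms <- evidence_time_ms()
  t_s <- t_ms / 1000
  base <- 2 * sin(2 * pi * 12.5 * t_s)
  e1 <- uniform_epoch(base, t_ms = t_ms)
  spec1 <- stft_amplitude(e1, channels = "C3")
  mb1 <- mu_beta_amplitude(spec1)
  # adding a pure 25 Hz component leaves the mu-beta measure unchanged
  e2 <- uniform_epoch(base + 5 * sin(2 * pi * (fs_hz / 205 * 10) * t_s),
                      t_ms = t_ms)
  mb2 <- mu_beta_amplitude(stft_amplitude(e2, channels = "C3"))
  expect_equal(mb1$amplitude, mb2$amplitude, tolerance = 0.02)

  lr <- mu_beta(spec1, stft_amplitude(e1, channels = "C4"), "left")
  # left-hand response: the right hemisphere is contralateral
  expect_identical(lr$mb_contra$amplitude,
                   mu_beta_amplitude(stft_amplitude(e1, channels = "C4"))$amplitude)
  rl <- mu_beta(spec1, stft_amplitude(e1, channels = "C4"), "right")
  expect_identical(rl$mb_contra$amplitude, mb1$amplitude)

  # symmetric signals: zero lateralisation
  expect_equal(lr$mb_contra$amplitude - lr$mb_ipsi$amplitude,
               rep(0, length(mb1$amplitude)), tolerance = 1e-9)
})

test_that("alpha extraction uses the 360 ms window over the 8-14 Hz band", {
  t_ms <- seq(-1699.219, 500, by = 1000 / fs_hz)
  t_s <- t_ms / 1000
  burst <- ifelse(t_ms >= -600 & t_ms < -200, 1, 0) *
    3 * sin(2 * pi * 10 * t_s)
  spec <- stft_amplitude(uniform_epoch(burst, t_ms = t_ms, alignment = "cue"),
                         channels = "POz", window_ms = 360)
  a <- alpha_band(spec)
  inside <- a$times_ms >= -400 & a$times_ms <= -300
  outside <- a$times_ms >= 100 & a$times_ms <= 400
  expect_gt(mean(a$amplitude[inside]), 5 * mean(a$amplitude[outside]))

  silent <- alpha_band(stft_amplitude(
    uniform_epoch(numeric(length(t_ms)), t_ms = t_ms), channels = "POz",
    window_ms = 360))
  expect_true(all(silent$amplitude == 0))
})

test_that("SSVEP electrode selection finds the injected channels", {
  prep <- shared_prep()
  pools <- electrode_pools()
  sel <- select_ssvep_electrodes(prep$evidence, pools$occipital)
  # the generator focuses the SSVEP on Oz and its immediate neighbours
  expect_true(all(sel$channels %in% c("Oz", "O1", "O2", "POz")))
  expect_length(sel$channels, 2L)

  # identical channels: deterministic tie-break on candidate order
  t_ms <- evidence_time_ms()
  flat <- lapply(1:3, function(i)
    make_epoch(matrix(1e-6, 37, length(t_ms)), t_ms = t_ms,
               trial = list(target_tag_hz = 20)))
  sel2 <- select_ssvep_electrodes(flat, pools$occipital)
  expect_identical(sel2$channels, pools$occipital[1:2])
})

test_that("mu-beta electrode selection scores both criteria and matches brute force", {
  prep <- shared_prep()
  pools <- electrode_pools()
  sel <- select_mb_electrodes(prep$response, pools)
  expect_true("C3" %in% sel$left)
  expect_true("C4" %in% sel$right)
  expect_false(sel$low_confidence)

  # rank-sum equals a brute-force enumeration of the two criteria
  sc <- sel$scores$left
  brute <- rank(-sc$amp_diff, ties.method = "first") +
    rank(-sc$neg_slope, ties.method = "first")
  expect_identical(unname(sc$rank_sum), unname(brute))

  # no lateralised signal: deterministic selection flagged low-confidence
  t_ms <- seq(-600, 398, by = 1000 / fs_hz)
  flat <- lapply(1:2, function(i)
    make_epoch(matrix(0, 37, length(t_ms)), t_ms = t_ms,
               alignment = "response",
               trial = list(response_side = c("left", "right")[i])))
  sel0 <- select_mb_electrodes(flat, pools)
  expect_true(sel0$low_confidence)
  expect_identical(sel0$left, pools$central_left[1:2])
})

test_that("noise-free extraction tracks the injected contrast difference", {
  sched <- generate_session(768, seed = 41, marginal_contrast_pct = 10)
  sched <- sched[sched$pulse_type == "none", ][1:20, ]
  sched$subject_id <- "S01"
  sched$trial_uid <- sprintf("S01_%04d", sched$trial_index)
  p <- gen_params(noise_rms_uv = 0, blink_rate_hz = 0, mb_amplitude_uv = 0,
                  alpha_engagement = c(valid = 0, invalid = 0, neutral = 0),
                  seed = 41)
  rs <- vapply(seq_len(nrow(sched)), function(i) {
    tr <- sched[i, ]
    tc <- contrast_timecourse(tr)
    e <- simulate_trial_eeg(tr, tc, p)
    ev <- ssvepcue:::cut_window(e, 0, -400, 2000, "evidence")
    spec <- stft_amplitude(ev, channels = c("Oz", "O1", "O2"))
    f_t <- tr$target_tag_hz
    marg <- marginal_ssvep(ssvep_normalized(spec, f_t),
                           ssvep_normalized(spec, setdiff(c(20, 25), f_t)))
    # injected contrast difference, window-averaged onto the STFT grid
    half <- spec$n_window_samples * (1000 / fs_hz) / 2
    injected <- vapply(marg$times_ms, function(mid) {
      idx <- ev$t_ms >= mid - half & ev$t_ms < mid + half
      tt <- ev$t_ms[idx] + 1200
      ci <- findInterval(tt, tc$time_ms)
      mean(tc$contrast_target_pct[ci] - tc$contrast_nontarget_pct[ci])
    }, numeric(1))
    cor(marg$amplitude, injected)
  }, numeric(1))
  expect_gt(min(rs), 0.99)
})
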