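test_that("pulse onsets follow the staggered design", {
  on <- pulse_onsets()
  expect_identical(on, seq(180L, 500L, by = 80L))
  expect_length(on, 5L)
  expect_true(all(diff(on) == 80L))
})

test_that("session schedules satisfy the cue and pulse composition", {
  for (case in list(list(n = 768, seed = 1), list(n = 1152, seed = 2),
                    list(n = 100, seed = 3))) {
    s <- generate_session(case$n, seed = case$seed)
    expect_equal(nrow(s), case$n)
    counts <- table(s$cue)
    # valid four times as frequent as invalid; invalid equals neutral
    if (case$n %% 6 == 0) {
      expect_equal(unname(counts["valid"]), 4 * unname(counts["invalid"]))
    }
    expect_equal(unname(counts["invalid"]), unname(counts["neutral"]))
    # directional cues are 80% predictive
    dir <- s$cue != "neutral"
    expect_equal(mean(s$cue[dir] == "valid"), 0.8, tolerance = 0.02)
    # 16 pulse cells equally represented (exact at multiples of 16)
    cell <- paste(s$pulse_type, s$pulse_onset_ms)
    if (case$n %% 16 == 0) {
      expect_true(all(table(cell) == case$n / 16))
    } else {
      expect_lte(diff(range(table(cell))), 1)
    }
    # tag counterbalance within every cue x pulse cell
    grp <- paste(s$cue, cell)
    imbalance <- tapply(s$target_tag_hz, grp,
                        function(x) abs(sum(x == 20) - sum(x == 25)))
    expect_lte(max(imbalance), 1)
  }
})

test_that("schedules are deterministic given the seed and error below 16 trials", {
  expect_identical(generate_session(96, seed = 7), generate_session(96, seed = 7))
  expect_false(identical(generate_session(96, seed = 7),
                         generate_session(96, seed = 8)))
  expect_error(generate_session(15), "at least 16")
})

test_that("each pulse cell appears exactly once at the minimum session size", {
  s <- generate_session(16, seed = 5)
  expect_true(all(table(paste(s$pulse_type, s$pulse_onset_ms)) == 1))
})

test_that("contrast time courses are reciprocal with a monotone fade-in", {
  s <- generate_session(16, seed = 9, marginal_contrast_pct = 10)
  for (i in seq_len(nrow(s))) {
    tc <- contrast_timecourse(s[i, ])
    on_screen <- tc$time_ms >= tc$phase_markers["baseline"]
    expect_true(all(abs(tc$contrast_target_pct[on_screen] +
                        tc$contrast_nontarget_pct[on_screen] - 100) < 1e-12))
    fade <- tc$time_ms < tc$phase_markers["baseline"]
    expect_true(all(diff(tc$contrast_target_pct[fade]) > 0))
    expect_true(all(tc$contrast_target_pct >= 0 &
                    tc$contrast_target_pct <= 100))
  }
})

test_that("pulses modify the evidence exactly as the task defines", {
  base <- generate_session(16, seed = 11, marginal_contrast_pct = 10)
  ev0 <- 1200   # evidence onset on the fade-in-anchored axis
  pick <- function(type) {
    r <- base[base$pulse_type == type, ][1, ]
    r$pulse_onset_ms <- 260L
    r
  }
  during <- function(tc) {
    idx <- tc$time_ms >= ev0 + 260 & tc$time_ms < ev0 + 410
    list(t = unique(tc$contrast_target_pct[idx]),
         n = unique(tc$contrast_nontarget_pct[idx]))
  }
  rev <- during(contrast_timecourse(pick("reverse")))
  expect_equal(rev$t, 40)
  expect_equal(rev$n, 60)
  gap <- during(contrast_timecourse(pick("gap")))
  expect_equal(gap$t, 50)
  expect_equal(gap$n, 50)
  pos <- during(contrast_timecourse(pick("positive")))
  expect_equal(pos$t, 70)
  expect_equal(pos$n, 30)
  # evidence reverts after the pulse
  tc <- contrast_timecourse(pick("reverse"))
  after <- tc$time_ms >= ev0 + 410
  expect_true(all(tc$contrast_target_pct[after] == 60))
  # positive pulse must stay inside [0, 100]
  infeasible <- pick("positive")
  infeasible$marginal_contrast_pct <- 30
  expect_error(contrast_timecourse(infeasible), "infeasible")
})

identical_or <- function(x, v) if (is.na(v)) is.na(x) else !is.na(x) & x == v

test_that("trial replacement appends replicas and triples as designed", {
  s <- generate_session(96, seed = 13)
  # idempotent with no early responses
  none <- data.frame(trial_index = integer(0), rt_ms = numeric(0))
  expect_identical(apply_replacement(s, none), s)

  # response before evidence onset: one replica at the end of the block
  r1 <- data.frame(trial_index = 5L, rt_ms = -120)
  out1 <- apply_replacement(s, r1, seed = 2)
  expect_equal(nrow(out1), nrow(s) + 1L)
  src <- s[5, ]
  matches <- out1[out1$cue == src$cue & out1$pulse_type == src$pulse_type &
                  out1$block == src$block &
                  identical_or(out1$pulse_onset_ms, src$pulse_onset_ms) &
                  out1$target_tag_hz == src$target_tag_hz &
                  out1$target_tilt == src$target_tilt, ]
  expect_gte(nrow(matches), 2)   # source + replica share the block
  # the replica sits at the end of its block
  blk <- out1[out1$block == src$block, ]
  expect_equal(utils::tail(blk$cue, 1), src$cue)
  expect_false(any(out1$immutable))

  # response before pulse onset: the extra block grows by a triple with
  # exactly one immutable replica
  pk <- which(s$pulse_type != "none")[1]
  r2 <- data.frame(trial_index = pk, rt_ms = s$pulse_onset_ms[pk] - 50)
  out2 <- apply_replacement(s, r2, seed = 3)
  expect_equal(nrow(out2), nrow(s) + 3L)
  extra <- out2[out2$block > max(s$block), ]
  expect_equal(nrow(extra), 3L)
  expect_equal(sum(extra$immutable), 1L)
  rep_row <- extra[extra$immutable, ]
  expect_equal(rep_row$cue, s$cue[pk])
  expect_equal(rep_row$pulse_onset_ms, s$pulse_onset_ms[pk])
  others <- extra[!extra$immutable, ]
  expect_true(all(others$cue != s$cue[pk] |
                  others$pulse_onset_ms != s$pulse_onset_ms[pk]))

  # a further pre-pulse response with a pulse type not yet in the extra
  # block swaps a mutable trial for a replica
  pk2 <- which(s$pulse_type != "none" &
               s$pulse_type != s$pulse_type[pk])[1]
  r3 <- rbind(r2, data.frame(trial_index = pk2,
                             rt_ms = s$pulse_onset_ms[pk2] - 60))
  out3 <- apply_replacement(s, r3, seed = 3)
  expect_equal(nrow(out3), nrow(s) + 3L)
  extra3 <- out3[out3$block > max(s$block), ]
  expect_equal(sum(extra3$immutable), 2L)

  # a second response sharing the first's pulse type (already >20% of the
  # extra block) adds a fresh triple instead
  pk3 <- which(s$pulse_type == s$pulse_type[pk])[2]
  r4 <- rbind(r2, data.frame(trial_index = pk3,
                             rt_ms = s$pulse_onset_ms[pk3] - 40))
  out4 <- apply_replacement(s, r4, seed = 3)
  expect_equal(nrow(out4), nrow(s) + 6L)
})

test_that("responses are scored with the task's points and outcome labels", {
  expect_equal(score_response(TRUE, 900)$points_delta, 50L)
  expect_equal(score_response(TRUE, 900)$outcome, "correct")
  expect_equal(score_response(FALSE, 900)$points_delta, -25L)
  expect_equal(score_response(FALSE, 900)$outcome, "error")
  expect_equal(score_response(TRUE, NA)$outcome, "too_slow")
  expect_equal(score_response(TRUE, NA)$points_delta, -25L)
  expect_equal(score_response(TRUE, -50)$outcome, "too_fast")
  expect_equal(score_response(TRUE, 2000)$outcome, "too_slow")
})

test_that("schedules round-trip through CSV", {
  s <- generate_session(48, seed = 21)
  path <- tempfile(fileext = ".csv")
  write_schedule(s, path)
  s2 <- read_schedule(path)
  expect_equal(as.data.frame(s)$cue, s2$cue)
  expect_equal(as.data.frame(s)$pulse_onset_ms, s2$pulse_onset_ms)
  expect_equal(as.data.frame(s)$marginal_contrast_pct,
               s2$marginal_contrast_pct)
})
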