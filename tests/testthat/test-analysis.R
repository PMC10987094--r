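test_that("task-exposure quintiles are equal-count with the remainder earliest", {
  expect_equal(table(bin_task_exposure(100)),
               table(rep(1:5, each = 20)), ignore_attr = TRUE)
  b <- bin_task_exposure(103)
  expect_equal(as.integer(table(b)), c(21, 21, 21, 20, 20))
  # chronological ordering preserved
  expect_true(all(diff(b) >= 0))
  expect_error(bin_task_exposure(4), "at least 5")
})

test_that("the analysis table derives exposure bins and the cued factor", {
  tab <- build_analysis_table(simulate_measures_table(3, 50, seed = 1))
  expect_true(all(tab$task_exposure_bin %in% 1:5))
  per <- tapply(tab$task_exposure_bin, tab$subject_id,
                function(b) diff(range(table(b))))
  expect_true(all(per <= 1))
  expect_identical(levels(tab$cue), c("neutral", "valid", "invalid"))
  expect_true(all(tab$cue_directional[tab$cue != "neutral"] == "cued"))
})

test_that("fit_mixed returns the effect-table schema with Satterthwaite df", {
  tab <- build_analysis_table(simulate_measures_table(6, 90, seed = 5))
  r <- fit_mixed(tab, "marginal_ssvep_evidence", c("cue"),
                 contrasts_for = "cue")
  expect_s3_class(r$effects, "data.frame")
  expect_named(r$effects, c("model", "term", "F", "df1", "df2", "p"))
  expect_true(all(r$effects$F >= 0))
  expect_true(all(r$effects$df2 > 0))
  expect_equal(r$df_method, "satterthwaite")
  expect_equal(nrow(r$contrasts), 3L)

  # logistic link reports Wald tests
  ra <- fit_mixed(tab, "correct", c("cue"), link = "logit")
  expect_true(all(is.finite(ra$effects$F)))
  expect_true(all(ra$effects$df2 == Inf))
})

test_that("a constant response yields zero F statistics and contrasts", {
  tab <- build_analysis_table(simulate_measures_table(3, 30, seed = 7))
  tab$flat <- 1.5
  r <- fit_mixed(tab, "flat", c("cue"), contrasts_for = "cue")
  expect_true(all(r$effects$F == 0))
  expect_true(all(r$contrasts$delta == 0))
})

test_that("pairwise deltas reproduce condition-mean differences on balanced data", {
  # balanced two-condition design, no noise structure beyond residuals
  set.seed(11)
  n <- 288   # 6 subjects x 96 trials, 32 per cue: exactly balanced
  tab <- data.frame(
    subject_id = rep(sprintf("S%02d", 1:6), each = n / 6),
    session_index = 1, trial_index = 1:n,
    cue = rep(c("neutral", "valid", "invalid"), times = n / 3),
    pulse_type = "none", target_tag_hz = 20,
    y = rnorm(n), stringsAsFactors = FALSE
  )
  tab$y <- tab$y + c(neutral = 0, valid = 0.5, invalid = -0.25)[tab$cue]
  tab <- build_analysis_table(tab)
  r <- fit_mixed(tab, "y", c("cue"), contrasts_for = "cue")
  mm <- tapply(tab$y, tab$cue, mean)
  d <- r$contrasts
  expect_equal(d$delta[d$contrast == "neutral - valid"],
               unname(mm["neutral"] - mm["valid"]), tolerance = 1e-9)
  expect_equal(d$delta[d$contrast == "valid - invalid"],
               unname(mm["valid"] - mm["invalid"]), tolerance = 1e-9)
})

test_that("behaviour models recover the generator's cue-validity deltas", {
  tab <- build_analysis_table(simulate_measures_table(14, 700, seed = 13))
  res <- behaviour_analysis(tab)
  d <- res$rt_correct$contrasts
  dv <- -d$delta[d$contrast == "neutral - valid"]
  di <- -d$delta[d$contrast == "neutral - invalid"]
  expect_lt(abs(dv - (-0.043)), 0.012)
  expect_lt(abs(di - 0.085), 0.012)
  de <- res$rt_error$contrasts
  expect_lt(abs(-de$delta[de$contrast == "neutral - valid"] - 0.084), 0.02)
  # accuracy deltas on the logit scale
  da <- res$accuracy$contrasts
  expect_lt(abs(-da$delta[da$contrast == "neutral - valid"] - 0.184), 0.08)
  expect_lt(abs(-da$delta[da$contrast == "neutral - invalid"] - (-0.219)),
            0.08)
  # the full RT model exposes the validity-by-accuracy interaction
  eff <- res$rt_full$effects
  expect_lt(eff$p[eff$term == "cue:correct"], 0.001)
})

test_that("a static invalid-cue gain reduction is detected in most replicates", {
  p <- measures_params(cue_evidence_gain = c(valid = 1, invalid = 0.9,
                                             neutral = 1))
  hits <- vapply(1:100, function(seed) {
    tab <- build_analysis_table(
      simulate_measures_table(40, 144, p, seed = seed))
    r <- fit_mixed(tab, "marginal_ssvep_evidence",
                   c("cue", "pulse_type", "target_tag_hz"),
                   contrasts_for = "cue", model_name = "evidence_cue")
    d <- r$contrasts
    delta_iv <- -d$delta[d$contrast == "valid - invalid"]   # invalid - valid
    delta_iv < 0 && d$p[d$contrast == "valid - invalid"] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.80)
})

test_that("the SSVEP-to-behaviour link recovers coupling signs and breaks when shuffled", {
  p <- measures_params(ssvep_accuracy_beta = 0.4, ssvep_rt_beta_s = -0.05)
  tab <- build_analysis_table(simulate_measures_table(12, 600, p, seed = 17))
  res <- ssvep_behaviour_link(tab)
  expect_gt(res$accuracy_link$slope, 0)
  expect_lt(res$accuracy_link$effects$p[
    res$accuracy_link$effects$term == "marginal_ssvep_evidence"], 0.05)
  expect_lt(res$rt_link$slope, 0)
  expect_lt(res$rt_link$effects$p[
    res$rt_link$effects$term == "marginal_ssvep_evidence"], 0.05)
  # only trials slower than 680 ms enter the link models
  expect_true(all(tab$rt_s[tab$rt_s <= 0.68] %in% tab$rt_s))
  expect_lte(res$accuracy_link$n, sum(tab$rt_s > 0.68))

  # shuffling the SSVEP across trials destroys the link
  shuffled <- tab
  set.seed(19)
  shuffled$marginal_ssvep_evidence <-
    sample(shuffled$marginal_ssvep_evidence)
  res0 <- ssvep_behaviour_link(shuffled)
  expect_gt(res0$rt_link$effects$p[
    res0$rt_link$effects$term == "marginal_ssvep_evidence"], 0.05)
})

test_that("mu-beta and alpha models recover their injected pre-evidence effects", {
  p <- measures_params(mb_lateralization = 0.3, alpha_neutral_drop = 0.3)
  tab <- build_analysis_table(simulate_measures_table(10, 300, p, seed = 23))
  res <- mb_alpha_analyses(tab)
  mb <- res$mb_lateralization
  expect_lt(mb$effects$p[mb$effects$term == "cue_directional"], 0.01)
  # cued trials are more negative (stronger contralateral preparation)
  expect_gt(mb$contrasts$delta[mb$contrasts$contrast == "neutral - cued"], 0)
  al <- res$alpha
  expect_lt(al$effects$p[al$effects$term == "cue_directional"], 0.01)
  # neutral alpha is lower (greater desynchronisation / engagement)
  expect_lt(al$contrasts$delta[al$contrasts$contrast == "neutral - cued"], 0)
})

test_that("the marginal-contrast trend regression matches a least-squares oracle", {
  # declining titration: QUEST re-run on an observer whose threshold falls
  # across sessions (practice effect)
  th <- c(20, 17, 14, 12.5, 12)
  rows <- do.call(rbind, lapply(1:6, function(s) {
    est <- vapply(seq_along(th), function(b)
      quest_run(observer(threshold_pct = th[b]),
                seed = s * 100 + b)$estimate_pct, numeric(1))
    data.frame(subject_id = sprintf("S%02d", s), task_exposure_bin = 1:5,
               mean_marginal_contrast_pct = est)
  }))
  res <- marginal_contrast_trend(rows)
  expect_lt(res$slope, 0)
  expect_lt(res$p, 0.05)

  # brute-force least-squares oracle for slope and R^2
  x <- rows$task_exposure_bin
  y <- rows$mean_marginal_contrast_pct
  beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  yhat <- mean(y) + beta * (x - mean(x))
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  expect_equal(res$slope, beta, tolerance = 1e-9)
  expect_equal(res$r_squared, r2, tolerance = 1e-9)

  flat <- rows
  flat$mean_marginal_contrast_pct <- 15
  res0 <- suppressWarnings(marginal_contrast_trend(flat))
  expect_equal(res0$slope, 0, tolerance = 1e-9)
})

test_that("the shipped registry covers the full model battery", {
  reg <- yaml::read_yaml(system.file("analyses.yaml", package = "ssvepcue"))
  ops <- vapply(reg$analyses, `[[`, "", "operation")
  expect_setequal(ops, c("behaviour_analysis", "ssvep_analyses",
                         "ssvep_behaviour_link", "mb_alpha_analyses"))
  models <- unlist(lapply(reg$analyses, `[[`, "models"))
  expect_setequal(models, c(
    "rt_full", "rt_correct", "rt_error", "accuracy",
    "evidence_cue", "baseline_cued", "target_nontarget",
    "evidence_cue_exposure", "pre_post_response",
    "accuracy_link", "rt_link", "mb_lateralization", "alpha"))
  tab <- build_analysis_table(simulate_measures_table(6, 100, seed = 29))
  bat <- suppressWarnings(run_analysis_battery(tab))
  expect_setequal(names(bat$results), models)
  expect_true(all(c("model", "term", "F", "df1", "df2", "p") %in%
                  names(bat$summary)))
})
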