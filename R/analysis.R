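# Statistical battery: condition effects on behaviour, SSVEP, mu-beta and
# alpha, fitted as trial-level mixed models with a subject random
# intercept, Satterthwaite-approximated F tests, and uncorrected pairwise
# contrasts.

#' Bin task exposure into quintiles
#'
#' Divides each subject's chronologically ordered trials into five
#' equal-count bins (sizes differ by at most one; the remainder goes to
#' the earliest bins). Bin 1 is the subject's earliest exposure to the
#' task, bin 5 their latest.
#'
#' @param n Number of trials for one subject (chronological order).
#' @param n_bins Number of bins (default 5).
#' @return Integer vector of bin labels, non-decreasing.
#' @export
bin_task_exposure <- function(n, n_bins = 5L) {
  if (n < n_bins) stop("need at least ", n_bins, " trials to form bins")
  base <- n %/% n_bins
  extra <- n %% n_bins
  sizes <- base + (seq_len(n_bins) <= extra)
  rep(seq_len(n_bins), times = sizes)
}

#' Assemble the per-trial analysis table
#'
#' Adds the derived analysis columns to a trial-measures data frame:
#' `task_exposure_bin` (per-subject chronological quintiles),
#' `cue_directional` (valid and invalid collapsed to `"cued"` for the
#' pre-evidence analyses), and factor codings with the neutral cue as
#' reference.
#'
#' @param measures Data frame from [extract_trial_measures()] or
#'   [simulate_measures_table()] (needs `subject_id`, `session_index`,
#'   `trial_index`, `cue`).
#' @return The augmented data frame (class `analysis_table`).
#' @export
build_analysis_table <- function(measures) {
  df <- measures[order(measures$subject_id, measures$session_index,
                       measures$trial_index), , drop = FALSE]
  df$task_exposure_bin <- stats::ave(
    seq_len(nrow(df)), df$subject_id,
    FUN = function(i) bin_task_exposure(length(i)))
  # centred covariate so Type-III main effects are evaluated at
  # mid-exposure rather than extrapolated to bin 0
  df$task_exposure_c <- df$task_exposure_bin - 3
  df$cue <- factor(df$cue, levels = c("neutral", "valid", "invalid"))
  df$cue_directional <- factor(
    ifelse(df$cue == "neutral", "neutral", "cued"),
    levels = c("neutral", "cued"))
  df$pulse_type <- factor(df$pulse_type)
  df$target_tag_hz <- factor(df$target_tag_hz)
  class(df) <- c("analysis_table", "data.frame")
  df
}

#' Fit a trial-level mixed model
#'
#' Fits `response ~ fixed terms + (1 | subject_id)`. Identity-link models
#' use a linear mixed model with Satterthwaite-approximated denominator
#' degrees of freedom for the fixed-effect F tests; logit-link (binary)
#' models use a generalised linear mixed model with Wald chi-square tests
#' reported as F statistics on their numerator df (denominator df
#' `Inf`). Pairwise condition contrasts are uncorrected. When the random
#' intercept variance is estimated as singular (zero), the model is refit
#' with a fixed intercept only and a warning is raised; the `df_method`
#' field then reads `"residual"`.
#'
#' @param table An [build_analysis_table()] data frame.
#' @param response Response column name.
#' @param fixed Character vector of fixed-effect terms (model-formula
#'   syntax, e.g. `c("cue * task_exposure_c", "pulse_type")`).
#' @param link `"identity"` or `"logit"`.
#' @param contrasts_for Factor name for pairwise contrasts (`NULL` to
#'   skip).
#' @param model_name Label carried into the output.
#' @return A list with class `effect_table`: `effects` (data frame
#'   `model`, `term`, `F`, `df1`, `df2`, `p`), `contrasts` (data frame
#'   `contrast`, `delta`, `p`), `df_method`, `n`, and `fit` (the model
#'   object).
#' @export
fit_mixed <- function(table, response, fixed, link = c("identity", "logit"),
                      contrasts_for = NULL, model_name = response) {
  link <- match.arg(link)
  keep <- stats::complete.cases(
    table[, c(response, all.vars(stats::reformulate(fixed))), drop = FALSE])
  df <- droplevels(table[keep, , drop = FALSE])
  # drop terms involving factors that are constant in this subset
  constant <- vapply(all.vars(stats::reformulate(fixed)), function(v)
    is.factor(df[[v]]) && nlevels(df[[v]]) < 2L, logical(1))
  if (any(constant)) {
    dropped <- names(constant)[constant]
    fixed <- fixed[!vapply(fixed, function(tm)
      any(dropped %in% all.vars(stats::reformulate(tm))), logical(1))]
    if (length(fixed) == 0L) fixed <- "1"
  }
  df$.y <- df[[response]]

  if (stats::var(as.numeric(df$.y)) == 0) {
    # degenerate response: every F is zero and contrasts vanish
    terms <- attr(stats::terms(stats::reformulate(fixed)), "term.labels")
    eff <- data.frame(model = model_name, term = terms, F = 0,
                      df1 = NA_real_, df2 = NA_real_, p = 1,
                      stringsAsFactors = FALSE)
    ctr <- if (!is.null(contrasts_for)) {
      lv <- levels(df[[contrasts_for]])
      cmb <- utils::combn(lv, 2)
      data.frame(contrast = paste(cmb[1, ], "-", cmb[2, ]), delta = 0,
                 p = 1, stringsAsFactors = FALSE)
    } else data.frame(contrast = character(0), delta = numeric(0),
                      p = numeric(0))
    return(structure(list(effects = eff, contrasts = ctr,
                          df_method = "degenerate", n = nrow(df),
                          fit = NULL),
                     class = "effect_table"))
  }

  fml <- stats::as.formula(paste(".y ~", paste(fixed, collapse = " + "),
                                 "+ (1 | subject_id)"))
  df_method <- "satterthwaite"
  if (link == "identity") {
    fit <- tryCatch(
      suppressMessages(lmerTest::lmer(fml, data = df, REML = TRUE)),
      error = function(e) NULL)
    if (is.null(fit) || lme4::isSingular(fit)) {
      if (!is.null(fit)) {
        warning("singular random-intercept variance; refitting with a ",
                "fixed intercept (residual df)")
      }
      fit <- stats::lm(stats::as.formula(
        paste(".y ~", paste(fixed, collapse = " + "))), data = df)
      df_method <- "residual"
      an <- stats::anova(fit)
      an <- an[rownames(an) != "Residuals", , drop = FALSE]
      eff <- data.frame(model = model_name, term = rownames(an),
                        F = an[["F value"]], df1 = an$Df,
                        df2 = stats::df.residual(fit), p = an[["Pr(>F)"]],
                        stringsAsFactors = FALSE)
    } else {
      an <- stats::anova(fit, type = 3, ddf = "Satterthwaite")
      eff <- data.frame(model = model_name, term = rownames(an),
                        F = an[["F value"]], df1 = an$NumDF,
                        df2 = an$DenDF, p = an[["Pr(>F)"]],
                        stringsAsFactors = FALSE)
    }
  } else {
    df$.y <- as.numeric(df$.y)
    fit <- tryCatch(
      suppressWarnings(suppressMessages(
        lme4::glmer(fml, data = df, family = stats::binomial(),
                    control = lme4::glmerControl(calc.derivs = FALSE)))),
      error = function(e) NULL)
    if (is.null(fit) || lme4::isSingular(fit)) {
      if (!is.null(fit)) {
        warning("singular random-intercept variance; refitting as a ",
                "fixed-intercept logistic model")
      }
      fit <- suppressWarnings(stats::glm(
        stats::as.formula(paste(".y ~", paste(fixed, collapse = " + "))),
        data = df, family = stats::binomial()))
    }
    df_method <- "wald"
    an <- wald_type3(fit)
    eff <- data.frame(model = model_name, term = an$term,
                      F = an$chisq / an$df, df1 = an$df, df2 = Inf,
                      p = an$p, stringsAsFactors = FALSE)
  }

  ctr <- if (!is.null(contrasts_for)) {
    em <- suppressMessages(
      emmeans::emmeans(fit, specs = contrasts_for,
                       data = df, lmer.df = "satterthwaite"))
    pr <- as.data.frame(emmeans::contrast(em, method = "pairwise",
                                          adjust = "none"))
    data.frame(contrast = as.character(pr$contrast), delta = pr$estimate,
               p = pr$p.value, stringsAsFactors = FALSE)
  } else {
    data.frame(contrast = character(0), delta = numeric(0),
               p = numeric(0))
  }

  structure(list(effects = eff, contrasts = ctr, df_method = df_method,
                 n = nrow(df), fit = fit),
            class = "effect_table")
}

# Type-III Wald chi-square tests for a binomial fit (glmer or glm),
# grouping coefficient columns by model term.
wald_type3 <- function(fit) {
  b <- if (inherits(fit, "merMod")) lme4::fixef(fit) else stats::coef(fit)
  ok <- !is.na(b)
  V <- as.matrix(stats::vcov(fit))
  asgn <- attr(stats::model.matrix(fit), "assign")[ok]
  b <- b[ok]
  labs <- attr(stats::terms(fit), "term.labels")
  out <- lapply(seq_along(labs), function(i) {
    idx <- which(asgn == i)
    if (length(idx) == 0L) {
      return(data.frame(term = labs[i], chisq = NA_real_, df = 0L,
                        p = NA_real_, stringsAsFactors = FALSE))
    }
    L <- matrix(0, length(idx), length(b))
    L[cbind(seq_along(idx), idx)] <- 1
    chisq <- drop(t(L %*% b) %*% solve(L %*% V %*% t(L)) %*% (L %*% b))
    data.frame(term = labs[i], chisq = chisq, df = length(idx),
               p = stats::pchisq(chisq, length(idx), lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Shared inclusion rules.
rt_filter <- function(table, min_rt_s) {
  table[!is.na(table$rt_s) & table$rt_s > min_rt_s, , drop = FALSE]
}

#' Behavioural battery
#'
#' The reaction-time and accuracy models: a full RT model with the cue
#' validity by choice-accuracy interaction, separate RT models for
#' correct and error responses (cue validity crossed with task exposure),
#' and a binary logistic accuracy model. Trials with reaction times of
#' 100 ms or less are excluded; pulse type and target tag frequency enter
#' as control fixed effects.
#'
#' @param table An [build_analysis_table()] data frame.
#' @return A named list of `effect_table`s: `rt_full`, `rt_correct`,
#'   `rt_error`, `accuracy`.
#' @export
behaviour_analysis <- function(table) {
  tb <- rt_filter(table, 0.1)
  ctrl <- c("pulse_type", "target_tag_hz")
  list(
    rt_full = fit_mixed(tb, "rt_s",
                        c("cue * correct", ctrl),
                        contrasts_for = "cue", model_name = "rt_full"),
    rt_correct = fit_mixed(tb[tb$correct, ], "rt_s",
                           c("cue * task_exposure_c", ctrl),
                           contrasts_for = "cue",
                           model_name = "rt_correct"),
    rt_error = fit_mixed(tb[!tb$correct, ], "rt_s",
                         c("cue * task_exposure_c", ctrl),
                         contrasts_for = "cue", model_name = "rt_error"),
    accuracy = fit_mixed(tb, "correct",
                         c("cue * task_exposure_c", ctrl),
                         link = "logit", contrasts_for = "cue",
                         model_name = "accuracy")
  )
}

#' SSVEP battery
#'
#' The five marginal-SSVEP models: the cue-validity effect during
#' evidence presentation; the anticipatory (baseline-phase) cued vs
#' neutral model; the target/non-target amplitude model with the cue by
#' signal-role interaction; the cue validity by task exposure interaction
#' model; and the pre- vs post-response difference model. Evidence-locked
#' models exclude reaction times of 100 ms or less and carry pulse type
#' and tag frequency as controls.
#'
#' @param table An [build_analysis_table()] data frame.
#' @return A named list of `effect_table`s: `evidence_cue`,
#'   `baseline_cued`, `target_nontarget`, `evidence_cue_exposure`,
#'   `pre_post_response`.
#' @export
ssvep_analyses <- function(table) {
  tb <- rt_filter(table, 0.1)
  ctrl <- c("pulse_type", "target_tag_hz")

  long <- rbind(
    transform(tb, .amp = tb$ssvep_target_evidence, role = "target"),
    transform(tb, .amp = tb$ssvep_nontarget_evidence, role = "nontarget")
  )
  long$role <- factor(long$role, levels = c("target", "nontarget"))

  tb$ssvep_resp_diff <- tb$ssvep_post_response - tb$ssvep_pre_response

  list(
    evidence_cue = fit_mixed(tb, "marginal_ssvep_evidence",
                             c("cue", ctrl), contrasts_for = "cue",
                             model_name = "evidence_cue"),
    baseline_cued = fit_mixed(table, "marginal_ssvep_baseline",
                              c("cue_directional", "target_tag_hz"),
                              contrasts_for = "cue_directional",
                              model_name = "baseline_cued"),
    target_nontarget = fit_mixed(long, ".amp",
                                 c("cue * role", ctrl),
                                 model_name = "target_nontarget"),
    evidence_cue_exposure = fit_mixed(tb, "marginal_ssvep_evidence",
                                      c("cue * task_exposure_c", ctrl),
                                      contrasts_for = "cue",
                                      model_name = "evidence_cue_exposure"),
    pre_post_response = fit_mixed(tb, "ssvep_resp_diff",
                                  c("cue * task_exposure_c", ctrl),
                                  contrasts_for = "cue",
                                  model_name = "pre_post_response")
  )
}

#' SSVEP-to-behaviour link models
#'
#' Predicts single-trial choice accuracy (logistic) and reaction time
#' (linear) from the marginal SSVEP during evidence, restricted to trials
#' with reaction times greater than 680 ms so the measurement window
#' (680:975 ms) precedes the response; cue validity is included to
#' control for its effects.
#'
#' @param table An [build_analysis_table()] data frame.
#' @return A named list of `effect_table`s: `accuracy_link`, `rt_link`.
#'   Each carries the marginal-SSVEP slope in `$slope`.
#' @export
ssvep_behaviour_link <- function(table) {
  tb <- rt_filter(table, 0.68)
  acc <- fit_mixed(tb, "correct", c("marginal_ssvep_evidence", "cue"),
                   link = "logit", model_name = "accuracy_link")
  rt <- fit_mixed(tb, "rt_s", c("marginal_ssvep_evidence", "cue"),
                  model_name = "rt_link")
  acc$slope <- fixef_slope(acc$fit, "marginal_ssvep_evidence")
  rt$slope <- fixef_slope(rt$fit, "marginal_ssvep_evidence")
  list(accuracy_link = acc, rt_link = rt)
}

fixef_slope <- function(fit, name) {
  if (is.null(fit)) return(NA_real_)
  b <- if (inherits(fit, "merMod")) lme4::fixef(fit) else stats::coef(fit)
  unname(b[name])
}

#' Mu-beta and alpha battery
#'
#' Pre-evidence analyses on the cue-locked epoch, with valid and invalid
#' trials collapsed into a single cued condition (the measurement windows
#' precede evidence onset, so cue validity is undefined): mu-beta
#' lateralisation (cued vs neutral, crossed with task exposure) and alpha
#' amplitude (cued vs neutral). No reaction-time filter is applied.
#'
#' @param table An [build_analysis_table()] data frame.
#' @return A named list of `effect_table`s: `mb_lateralization`, `alpha`.
#' @export
mb_alpha_analyses <- function(table) {
  list(
    mb_lateralization = fit_mixed(
      table, "mb_lateralization_baseline",
      c("cue_directional * task_exposure_c"),
      contrasts_for = "cue_directional",
      model_name = "mb_lateralization"),
    alpha = fit_mixed(table, "alpha_pre", c("cue_directional"),
                      contrasts_for = "cue_directional",
                      model_name = "alpha")
  )
}

#' Marginal-contrast trend across task exposure
#'
#' Simple linear regression of the per-subject, per-exposure-bin mean
#' marginal contrast on the bin index, testing whether difficulty
#' titration reduced the physical evidence across testing.
#'
#' @param summaries Data frame with columns `subject_id`,
#'   `task_exposure_bin`, `mean_marginal_contrast_pct`.
#' @return A list: `slope`, `F`, `df1`, `df2`, `p`, `r_squared`, `fit`.
#' @export
marginal_contrast_trend <- function(summaries) {
  fit <- stats::lm(mean_marginal_contrast_pct ~ task_exposure_bin,
                   data = summaries)
  an <- stats::anova(fit)
  s <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       F = an[["F value"]][1], df1 = an$Df[1],
       df2 = stats::df.residual(fit), p = an[["Pr(>F)"]][1],
       r_squared = s$r.squared, fit = fit)
}

#' Run the registered analysis battery
#'
#' Executes every model in the shipped registry (`analyses.yaml`) on an
#' analysis table and returns the effect tables plus a flat CSV-ready
#' summary.
#'
#' @param table An [build_analysis_table()] data frame.
#' @param registry Path to the YAML registry (default: the shipped one).
#' @return A list: `results` (named `effect_table`s), `summary` (data
#'   frame with one row per fixed-effect test), `registry`.
#' @export
run_analysis_battery <- function(table,
                                 registry = system.file("analyses.yaml",
                                                        package = "ssvepcue")) {
  reg <- yaml::read_yaml(registry)
  results <- list()
  for (grp in names(reg$analyses)) {
    op <- reg$analyses[[grp]]$operation
    fn <- get(op, envir = asNamespace("ssvepcue"))
    res <- fn(table)
    stopifnot(all(reg$analyses[[grp]]$models %in% names(res)))
    results <- c(results, res)
  }
  summary <- do.call(rbind, lapply(names(results), function(nm) {
    results[[nm]]$effects
  }))
  list(results = results, summary = summary, registry = reg)
}

#' Write effect tables to CSV
#'
#' Fixed schema: `model`, `term`, `F`, `df1`, `df2`, `p`, plus one row
#' per pairwise contrast (`contrast`, `delta`, `p_contrast`).
#'
#' @param results Named list of `effect_table`s.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_effect_tables <- function(results, path) {
  rows <- lapply(names(results), function(nm) {
    r <- results[[nm]]
    eff <- r$effects
    eff$contrast <- NA_character_
    eff$delta <- NA_real_
    eff$p_contrast <- NA_real_
    if (nrow(r$contrasts) > 0) {
      ctr <- data.frame(model = nm, term = NA_character_, F = NA_real_,
                        df1 = NA_real_, df2 = NA_real_, p = NA_real_,
                        contrast = r$contrasts$contrast,
                        delta = r$contrasts$delta,
                        p_contrast = r$contrasts$p,
                        stringsAsFactors = FALSE)
      eff <- rbind(eff, ctr)
    }
    eff
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
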