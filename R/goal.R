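#' Derive prediction errors and prediction changes from diary entries
#'
#' For each completed activity the diary records a reward and punishment
#' prediction made when the activity was planned (`R_pre`, `P_pre`), the
#' experienced reward and punishment (`r`, `p`), and a fresh prediction
#' made right after completion (`R_post1`, `P_post1`). From these:
#' `delta_R = r - R_pre` and `delta_P = p - P_pre` are the prediction
#' errors; `dR1 = R_post1 - R_pre` and `dP1 = P_post1 - P_pre` the
#' immediate prediction changes; and `dR2`/`dP2` the long-timescale
#' changes — the difference between the predictions made at successive
#' plannings of the *same* activity, attached to the earlier planning
#' (absent for the last planning of an activity). `repeat_next_day` flags
#' whether the same activity was planned again for the following day.
#'
#' @param entries Diary tibble with `subject_id`, `day`, `activity_id`,
#'   `R_pre`, `P_pre`, `r`, `p`, `R_post1`, `P_post1` (plus any extra
#'   columns, carried through).
#' @return The entries augmented with `delta_R`, `delta_P`, `dR1`, `dP1`,
#'   `dR2`, `dP2`, `repeat_next_day`.
#' @export
derive_pe_table <- function(entries) {
  req <- c("subject_id", "day", "activity_id", "R_pre", "P_pre", "r", "p",
           "R_post1", "P_post1")
  missing <- setdiff(req, names(entries))
  if (length(missing)) {
    stop("diary lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  dup <- entries |>
    dplyr::count(.data$subject_id, .data$day, .data$activity_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    stop("duplicate (subject, day, activity) entries: ",
         paste(sprintf("%s/day %s/%s", dup$subject_id, dup$day,
                       dup$activity_id), collapse = "; "), call. = FALSE)
  }
  entries |>
    dplyr::arrange(.data$subject_id, .data$day) |>
    dplyr::mutate(
      delta_R = .data$r - .data$R_pre,
      delta_P = .data$p - .data$P_pre,
      dR1 = .data$R_post1 - .data$R_pre,
      dP1 = .data$P_post1 - .data$P_pre) |>
    dplyr::group_by(.data$subject_id, .data$activity_id) |>
    dplyr::arrange(.data$day, .by_group = TRUE) |>
    dplyr::mutate(
      dR2 = dplyr::lead(.data$R_pre) - .data$R_pre,
      dP2 = dplyr::lead(.data$P_pre) - .data$P_pre,
      repeat_next_day = !is.na(dplyr::lead(.data$day)) &
        dplyr::lead(.data$day) == .data$day + 1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$subject_id, .data$day)
}

# Fit a mixed model with per-subject random intercept and slope for one
# predictor, falling back to simpler random-effects structures on failure.
# Returns list(model, random_structure).
lmm_with_fallback <- function(formula_full, formula_indep, formula_intercept,
                              data, family = NULL) {
  fitter <- function(f) {
    if (is.null(family)) {
      lme4::lmer(f, data = data, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore"))
    } else {
      lme4::glmer(f, data = data, family = family,
                  control = lme4::glmerControl(check.conv.singular = "ignore"))
    }
  }
  try_fit <- function(f, strict) {
    tryCatch({
      fit <- suppressMessages(suppressWarnings(fitter(f)))
      conv <- fit@optinfo$conv$lme4
      if (strict && !is.null(conv$code) && conv$code != 0) NULL else fit
    }, error = function(e) NULL)
  }
  structures <- list(list(f = formula_full, nm = "correlated"),
                     list(f = formula_indep, nm = "independent"),
                     list(f = formula_intercept, nm = "intercept_only"))
  # prefer cleanly converged fits; accept flagged ones (e.g. the
  # zero-residual deterministic limit) only if no structure is clean
  for (strict in c(TRUE, FALSE)) {
    for (spec in structures) {
      fit <- try_fit(spec$f, strict)
      if (!is.null(fit)) {
        nm <- if (strict) spec$nm else paste0(spec$nm, "_flagged")
        return(list(model = fit, random_structure = nm))
      }
    }
  }
  stop("mixed model failed to fit under all random-effects structures",
       call. = FALSE)
}

goal_fit_result <- function(lf, analysis, extra = list()) {
  structure(
    c(wald_coefficients(lf$model),
      list(model = lf$model, random_structure = lf$random_structure,
           analysis = analysis),
      extra),
    class = "goal_fit")
}

#' @export
print.goal_fit <- function(x, ...) {
  cat("<goal_fit>", x$analysis, "\n")
  print(x$coefficients)
  cat("  random effects:", x$random_structure, "\n")
  invisible(x)
}

#' Does prediction change track the prediction error?
#'
#' Regresses a prediction-change measure (`dR1`, `dP1`, `dR2` or `dP2`)
#' on a prediction error (`delta_R` or `delta_P`) in a linear mixed model
#' with the predictor as fixed effect and per-subject random intercept and
#' slope (correlated by default; independent or intercept-only structures
#' are used as fallbacks and recorded). A slope near the cohort's typical
#' update rate, with Wald z well away from zero, is the reinforcement-
#' learning signature.
#'
#' @param table A [derive_pe_table()] result.
#' @param outcome One of `"dR1"`, `"dP1"`, `"dR2"`, `"dP2"`.
#' @param predictor One of `"delta_R"`, `"delta_P"`.
#' @return A `"goal_fit"` with the coefficient tibble (Wald z, p, 95% CI)
#'   and the random-effects structure used.
#' @export
fit_pe_update <- function(table, outcome = "dR1", predictor = "delta_R") {
  outcome <- match.arg(outcome, c("dR1", "dP1", "dR2", "dP2"))
  predictor <- match.arg(predictor, c("delta_R", "delta_P"))
  d <- table[stats::complete.cases(table[, c(outcome, predictor)]), ]
  if (length(unique(d$subject_id)) < 2) {
    stop("need at least 2 subjects", call. = FALSE)
  }
  d$.y <- d[[outcome]]
  d$.x <- d[[predictor]]
  lf <- lmm_with_fallback(
    .y ~ .x + (1 + .x | subject_id),
    .y ~ .x + (1 | subject_id) + (0 + .x | subject_id),
    .y ~ .x + (1 | subject_id), d)
  out <- goal_fit_result(lf, sprintf("%s ~ %s", outcome, predictor))
  out$coefficients$term <- sub("^\\.x", predictor, out$coefficients$term)
  out
}

#' Does yesterday's outcome drive repeating an activity?
#'
#' Mixed-effects logistic regression of whether the day's activity is
#' planned again for the next day on the reward and punishment reported
#' for it, with per-subject random effects. Complete separation (e.g.
#' every activity always repeated) is flagged instead of reported as a
#' huge coefficient.
#'
#' @param table A [derive_pe_table()] result.
#' @return A `"goal_fit"` with log-odds coefficients for `r` and `p`, and
#'   a `separation` flag.
#' @export
fit_repeat_choice <- function(table) {
  d <- table[stats::complete.cases(table[, c("repeat_next_day", "r", "p")]), ]
  rate <- mean(d$repeat_next_day)
  if (rate %in% c(0, 1)) {
    out <- list(coefficients = tibble::tibble(
      term = c("(Intercept)", "r", "p"), estimate = NA_real_,
      std_error = NA_real_, statistic = NA_real_, p_value = NA_real_,
      conf_low = NA_real_, conf_high = NA_real_),
      singular = NA, dropped_terms = character(0), model = NULL,
      random_structure = NA_character_,
      analysis = "repeat_next_day ~ r + p", separation = TRUE)
    class(out) <- "goal_fit"
    return(out)
  }
  lf <- lmm_with_fallback(
    repeat_next_day ~ r + p + (1 + r + p | subject_id),
    repeat_next_day ~ r + p + (1 | subject_id) + (0 + r | subject_id) +
      (0 + p | subject_id),
    repeat_next_day ~ r + p + (1 | subject_id),
    d, family = stats::binomial())
  out <- goal_fit_result(lf, "repeat_next_day ~ r + p")
  out$separation <- any(abs(out$coefficients$estimate) > 15)
  out
}

#' Is prediction-error updating stronger in subjects whose anhedonia
#' improved more?
#'
#' Adds a per-subject anhedonia-item change score (IDS-SR item 19, general
#' interest, or item 21, capacity for pleasure; change = end - start, so
#' improvements are negative) and its interaction with the prediction
#' error to the [fit_pe_update()] model. The interaction's p-value is
#' Bonferroni-corrected for the two item hypotheses
#' (`p_bonferroni = min(1, 2 p)`). The item change enters as a fixed
#' effect only (one value per subject).
#'
#' @inheritParams fit_pe_update
#' @param item_change Tibble with `subject_id` and `item_change`.
#' @return A `"goal_fit"`; the coefficient table carries `p_bonferroni`
#'   on the interaction row.
#' @export
fit_item_interaction <- function(table, item_change, outcome = "dR1",
                                 predictor = "delta_R") {
  outcome <- match.arg(outcome, c("dR1", "dP1", "dR2", "dP2"))
  predictor <- match.arg(predictor, c("delta_R", "delta_P"))
  if (!all(c("subject_id", "item_change") %in% names(item_change))) {
    stop("`item_change` needs columns subject_id, item_change", call. = FALSE)
  }
  if (sd(item_change$item_change) < 1e-12) {
    stop("`item_change` is constant across subjects: the interaction is ",
         "inestimable", call. = FALSE)
  }
  d <- dplyr::inner_join(table, item_change, by = "subject_id")
  d <- d[stats::complete.cases(d[, c(outcome, predictor, "item_change")]), ]
  d$.y <- d[[outcome]]
  d$.x <- d[[predictor]]
  lf <- lmm_with_fallback(
    .y ~ .x * item_change + (1 + .x | subject_id),
    .y ~ .x * item_change + (1 | subject_id) + (0 + .x | subject_id),
    .y ~ .x * item_change + (1 | subject_id), d)
  out <- goal_fit_result(
    lf, sprintf("%s ~ %s * item_change", outcome, predictor))
  out$coefficients$term <- sub("^\\.x", predictor, out$coefficients$term)
  out$coefficients$p_bonferroni <- ifelse(
    grepl(":item_change$", out$coefficients$term),
    pmin(1, 2 * out$coefficients$p_value), NA_real_)
  out
}

#' Baseline-score control for the anhedonia-item interaction
#'
#' Identical to [fit_item_interaction()] but with the item's *baseline*
#' score per subject in place of its change, to check whether an apparent
#' change-score interaction merely reflects baseline severity.
#'
#' @inheritParams fit_item_interaction
#' @param baseline Tibble with `subject_id` and `baseline`.
#' @return A `"goal_fit"`.
#' @export
fit_baseline_control <- function(table, baseline, outcome = "dR1",
                                 predictor = "delta_R") {
  if (!all(c("subject_id", "baseline") %in% names(baseline))) {
    stop("`baseline` needs columns subject_id, baseline", call. = FALSE)
  }
  ic <- tibble::tibble(subject_id = baseline$subject_id,
                       item_change = baseline$baseline)
  out <- fit_item_interaction(table, ic, outcome, predictor)
  out$analysis <- sub("item_change", "item_baseline", out$analysis)
  out
}

#' Per-subject diary update slopes
#'
#' Ordinary least-squares slope of a prediction change on a prediction
#' error, one per subject — a simple subject-level summary of how strongly
#' the diary follows reinforcement-learning updating, used e.g. to
#' correlate with task-derived learning rates.
#'
#' @inheritParams fit_pe_update
#' @return Tibble with `subject_id`, `slope`, `n`.
#' @export
subject_update_slopes <- function(table, outcome = "dR1",
                                  predictor = "delta_R") {
  d <- table[stats::complete.cases(table[, c(outcome, predictor)]), ]
  d |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      slope = if (dplyr::n() >= 3 && sd(.data[[predictor]]) > 0) {
        stats::cov(.data[[outcome]], .data[[predictor]]) /
          var(.data[[predictor]])
      } else NA_real_,
      n = dplyr::n(), .groups = "drop")
}

#' Correlate task-derived and diary-derived learning rates
#'
#' @param task_rates Tibble with `subject_id` and `value` (e.g. fitted
#'   `alpha`).
#' @param diary_rates Tibble with `subject_id` and `value` (e.g. slopes
#'   from [subject_update_slopes()]).
#' @return Tibble with one row per method (`pearson`, `spearman`):
#'   `estimate`, `p_value`, `n`, `degenerate` (constant input).
#' @export
correlate_learning_rates <- function(task_rates, diary_rates) {
  d <- dplyr::inner_join(task_rates, diary_rates, by = "subject_id",
                         suffix = c("_task", "_diary"))
  d <- d[stats::complete.cases(d[, c("value_task", "value_diary")]), ]
  if (nrow(d) < 3) stop("need at least 3 subjects with both values",
                        call. = FALSE)
  degenerate <- sd(d$value_task) < 1e-12 || sd(d$value_diary) < 1e-12
  one <- function(method) {
    if (degenerate) {
      return(tibble::tibble(method = method, estimate = NA_real_,
                            p_value = NA_real_, n = nrow(d),
                            degenerate = TRUE))
    }
    ct <- suppressWarnings(cor.test(d$value_task, d$value_diary,
                                    method = method))
    tibble::tibble(method = method, estimate = unname(ct$estimate),
                   p_value = ct$p.value, n = nrow(d), degenerate = FALSE)
  }
  dplyr::bind_rows(one("pearson"), one("spearman"))
}
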