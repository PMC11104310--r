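#' Design matrix for the symptom-trajectory regression
#'
#' Weekly total depression scores are modelled as a per-subject mean
#' (random intercept) plus four fixed effects: a step improvement after
#' the reward-focused therapy phase (`step3 = 1[week >= t3_week]`), a step
#' improvement after the avoidance-focused phase
#' (`step7 = 1[week >= t7_week]`), and improvements proportional to each
#' subject's change in the appetitive and aversive Pavlovian parameters
#' (`app_change_x = delta_pi_app * step3`,
#' `av_change_x = delta_pi_av * step7`).
#'
#' @param series Symptom tibble with `subject_id`, `week`, `ids_total`.
#' @param changes Tibble with `subject_id`, `delta_pi_app`, `delta_pi_av`
#'   (use [parameter_changes()] to extract them from a task fit).
#' @param t3_week,t7_week Weeks at which the two phases take effect
#'   (defaults 4 and 7, matching task administrations 3 and 4).
#' @return The series joined with columns `step3`, `step7`,
#'   `app_change_x`, `av_change_x`. Subjects without change scores are
#'   dropped with a warning.
#' @export
build_symptom_design <- function(series, changes, t3_week = 4, t7_week = 7) {
  req <- c("subject_id", "delta_pi_app", "delta_pi_av")
  if (!all(req %in% names(changes))) {
    stop("`changes` needs columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(unique(series$subject_id), changes$subject_id)
  if (length(missing)) {
    warning("dropping subject(s) without parameter-change scores: ",
            paste(missing, collapse = ", "), call. = FALSE)
  }
  series |>
    dplyr::inner_join(changes[, req], by = "subject_id") |>
    dplyr::mutate(
      step3 = as.numeric(.data$week >= t3_week),
      step7 = as.numeric(.data$week >= t7_week),
      app_change_x = .data$delta_pi_app * .data$step3,
      av_change_x = .data$delta_pi_av * .data$step7)
}

#' Mixed-effects regression of symptom trajectories on parameter changes
#'
#' Fits `ids_total ~ step3 + step7 + app_change_x + av_change_x +
#' (1 | subject_id)` by REML ([lme4::lmer()]) on the design from
#' [build_symptom_design()]. Negative weights on the two parameter-change
#' regressors mean that subjects whose Pavlovian weight increased more
#' after the corresponding therapy phase improved more. Wald z tests and
#' 95% confidence intervals are reported; small-sample exactness is not
#' attempted.
#'
#' @inheritParams build_symptom_design
#' @param outcome Column of `series` to model (default `"ids_total"`).
#' @return An object of class `"symptom_fit"`: coefficient tibble
#'   (`term`, `estimate`, `std_error`, `statistic`, `p_value`, `conf_low`,
#'   `conf_high`), the `lmer` model, the design, and flags `singular` and
#'   `dropped_terms` (regressors inestimable in a degenerate design, e.g.
#'   all-zero change scores).
#' @export
fit_symptom_model <- function(series, changes, t3_week = 4, t7_week = 7,
                              outcome = "ids_total") {
  design <- build_symptom_design(series, changes, t3_week, t7_week)
  if (length(unique(design$subject_id)) < 2) {
    stop("need at least 2 subjects", call. = FALSE)
  }
  design$.outcome <- design[[outcome]]
  fit <- suppressMessages(lme4::lmer(
    .outcome ~ step3 + step7 + app_change_x + av_change_x + (1 | subject_id),
    data = design, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore")))
  structure(
    c(wald_coefficients(fit),
      list(model = fit, design = design, outcome = outcome,
           t3_week = t3_week, t7_week = t7_week)),
    class = "symptom_fit")
}

# Wald z coefficient table for a merMod fit, flagging dropped
# (rank-deficient) columns and singular fits.
wald_coefficients <- function(fit) {
  beta <- lme4::fixef(fit)
  # vcov can fail in degenerate (e.g. zero-residual) fits; keep the
  # estimates and report NA uncertainty in that case
  se <- tryCatch(sqrt(diag(as.matrix(vcov(fit)))),
                 error = function(e) rep(NA_real_, length(beta)))
  z <- beta / se
  all_terms <- colnames(stats::model.matrix(fit))
  coefs <- tibble::tibble(
    term = names(beta), estimate = unname(beta), std_error = unname(se),
    statistic = unname(z), p_value = 2 * pnorm(-abs(unname(z))),
    conf_low = unname(beta - qnorm(0.975) * se),
    conf_high = unname(beta + qnorm(0.975) * se))
  list(coefficients = coefs,
       singular = lme4::isSingular(fit),
       dropped_terms = setdiff(all_terms, names(beta)))
}

#' @export
print.symptom_fit <- function(x, ...) {
  cat("<symptom_fit> outcome:", x$outcome, "\n")
  print(x$coefficients)
  if (x$singular) cat("  note: singular random-effects fit\n")
  if (length(x$dropped_terms)) {
    cat("  dropped (inestimable):", paste(x$dropped_terms, collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Null-variant symptom regression with substituted change scores
#'
#' Refits the symptom-trajectory model with alternative per-subject change
#' scores (e.g. changes in the learning rate or lapse instead of the
#' Pavlovian weights, or permuted Pavlovian changes) standing in the
#' `delta_pi_app` / `delta_pi_av` slots. All-zero scores are flagged
#' degenerate.
#'
#' @inheritParams fit_symptom_model
#' @param null_changes Tibble with `subject_id` and two change-score
#'   columns, named by `score_cols`.
#' @param score_cols The two columns of `null_changes` standing in for the
#'   appetitive and aversive change scores.
#' @return A `"symptom_fit"` (with `null_scores` recording the
#'   substitution).
#' @export
null_variant_fit <- function(series, null_changes,
                             score_cols = c("delta_alpha", "delta_xi"),
                             t3_week = 4, t7_week = 7,
                             outcome = "ids_total") {
  stopifnot(length(score_cols) == 2, all(score_cols %in% names(null_changes)))
  sub <- tibble::tibble(
    subject_id = null_changes$subject_id,
    delta_pi_app = null_changes[[score_cols[1]]],
    delta_pi_av = null_changes[[score_cols[2]]])
  if (all(abs(sub$delta_pi_app) < 1e-12) ||
      all(abs(sub$delta_pi_av) < 1e-12)) {
    warning("all-zero change scores: the substituted regressors are ",
            "degenerate", call. = FALSE)
  }
  out <- fit_symptom_model(series, sub, t3_week, t7_week, outcome)
  out$null_scores <- score_cols
  out
}

#' Per-subject parameter-change scores from a hierarchical fit
#'
#' @param fit A [em_fit()] of a session-varying model.
#' @return Tibble with `subject_id`, `delta_pi_app`
#'   (`pi_app_post - pi_app`) and `delta_pi_av` (`pi_av_post - pi_av`).
#' @export
parameter_changes <- function(fit) {
  stopifnot(inherits(fit, "gng_fit"))
  if (!fit$spec$session_varying) {
    stop("parameter changes require a session-varying model", call. = FALSE)
  }
  purrr::imap(fit$subject_fits, function(sf, sid) {
    p <- sf$par_natural
    tibble::tibble(subject_id = sid,
                   delta_pi_app = p[["pi_app_post"]] - p[["pi_app"]],
                   delta_pi_av = p[["pi_av_post"]] - p[["pi_av"]])
  }) |> dplyr::bind_rows()
}
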