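#' Tidy a hierarchical task-model fit
#'
#' @param x A [em_fit()] result.
#' @param what `"subjects"` (default) for per-subject MAP estimates on the
#'   natural scale, `"prior"` for the fitted group prior (transformed
#'   scale).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.gng_fit <- function(x, what = c("subjects", "prior"), ...) {
  what <- match.arg(what)
  if (what == "prior") return(tibble::as_tibble(x$prior))
  purrr::imap(x$subject_fits, function(sf, sid) {
    tibble::tibble(subject_id = sid, parameter = names(sf$par_natural),
                   estimate = unname(sf$par_natural),
                   transformed = unname(sf$par),
                   std_error_transformed = sqrt(unname(sf$posterior_var)))
  }) |> dplyr::bind_rows()
}

#' Glance at a hierarchical task-model fit
#'
#' @param x A [em_fit()] result.
#' @param ... Unused.
#' @return One-row tibble with model name, subject/trial counts, EM
#'   iterations, convergence, log marginal likelihood, iBIC and mean
#'   posterior choice probability.
#' @export
glance.gng_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model, n_subjects = x$n_subjects, n_trials = x$n_trials,
    em_iterations = x$em_iterations, converged = x$converged,
    log_marginal = x$log_marginal, ibic = x$ibic,
    mean_choice_prob = x$mean_choice_prob)
}

#' Tidy a symptom-trajectory regression
#'
#' @param x A [fit_symptom_model()] result.
#' @param ... Unused.
#' @return The Wald coefficient tibble.
#' @export
tidy.symptom_fit <- function(x, ...) x$coefficients

#' @rdname tidy.symptom_fit
#' @export
glance.symptom_fit <- function(x, ...) {
  tibble::tibble(
    outcome = x$outcome, n_obs = nrow(x$design),
    n_subjects = length(unique(x$design$subject_id)),
    singular = x$singular, n_dropped_terms = length(x$dropped_terms))
}

#' Tidy a diary (GOAL-form) mixed-model fit
#'
#' @param x A `"goal_fit"` from [fit_pe_update()], [fit_repeat_choice()],
#'   [fit_item_interaction()] or [fit_baseline_control()].
#' @param ... Unused.
#' @return The Wald coefficient tibble.
#' @export
tidy.goal_fit <- function(x, ...) x$coefficients

#' @rdname tidy.goal_fit
#' @export
glance.goal_fit <- function(x, ...) {
  tibble::tibble(
    analysis = x$analysis, random_structure = x$random_structure,
    singular = isTRUE(x$singular),
    separation = isTRUE(x$separation))
}
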