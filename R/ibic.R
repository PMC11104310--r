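#' Integrated BIC of a hierarchical fit
#'
#' The group-level marginal likelihood integrates each subject's likelihood
#' over the fitted Gaussian prior; it is estimated by Monte Carlo, averaging
#' the likelihood of `n_samples` parameter draws from the prior per subject
#' (log-sum-exp stabilized). The integrated BIC then penalizes the prior's
#' parameter count (a mean and a variance per model parameter) with the
#' total number of choices as sample size:
#' `iBIC = -2 * log_marginal + 2 * n_params * log(n_trials)`. Lower is
#' better.
#'
#' @param fit A [em_fit()] result (its prior and spec are used).
#' @param data The cohort trial tibble the model was fitted to.
#' @param n_samples Prior draws per subject (default 2000; fewer than 100
#'   triggers a high-variance warning).
#' @param seed Optional seed.
#' @return The iBIC (scalar), with attributes `log_marginal`,
#'   `per_subject` (log marginals) and `n_prior_params`.
#' @export
integrated_bic <- function(fit, data, n_samples = 2000, seed = NULL) {
  if (n_samples < 100) {
    warning("n_samples < 100 gives a high-variance marginal estimate",
            call. = FALSE)
  }
  spec <- fit$spec
  prior <- fit$prior
  subjects <- split(data, data$subject_id)
  to_nat <- make_untransformer(prior$parameter)
  to_slots <- make_slot_builder(spec, prior$parameter)
  per_subject <- with_seed(seed, {
    vapply(subjects, function(d) {
      m <- marshal_trials(d)
      draws <- draw_from_prior(prior, n_samples)
      ll <- vapply(seq_len(n_samples), function(k) {
        sum(cpp_trial_loglik(m$condition, m$valence_win, m$action_go,
                             m$outcome, m$administration, m$learn,
                             to_slots(to_nat(draws[k, ]))))
      }, numeric(1))
      mx <- max(ll)
      mx + log(mean(exp(ll - mx)))
    }, numeric(1))
  })
  log_marginal <- sum(per_subject)
  n_prior_params <- 2L * nrow(prior)
  ibic <- -2 * log_marginal + n_prior_params * log(nrow(data))
  structure(ibic, log_marginal = log_marginal, per_subject = per_subject,
            n_prior_params = n_prior_params)
}

#' Fit and compare a set of models by integrated BIC
#'
#' Each candidate model is fitted to the cohort with [em_fit()]; models are
#' ranked by iBIC (lower = more parsimonious), and the mean per-trial
#' posterior probability of the observed choices at the subject MAPs is
#' reported as a raw goodness-of-fit measure. Models that fail to fit are
#' recorded and excluded from the ranking with a warning.
#'
#' @param data Cohort trial tibble.
#' @param specs List of [model_spec()] objects (named, or names are taken
#'   from [model_name()]); see [model_set()].
#' @param seed Optional seed, split across models.
#' @param ... Passed to [em_fit()] (e.g. `tol`, `ibic_samples`).
#' @return A tibble of class `"gng_model_comparison"` sorted by iBIC, with
#'   columns `model`, `n_params`, `ibic`, `delta_ibic`, `mean_choice_prob`,
#'   `converged`; fitted objects in `attr(, "fits")`.
#' @export
compare_models <- function(data, specs = model_set(), seed = NULL, ...) {
  if (length(specs) < 2) stop("need at least 2 models", call. = FALSE)
  if (is.null(names(specs))) {
    names(specs) <- vapply(specs, model_name, character(1))
  }
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, length(specs)))
  fits <- vector("list", length(specs))
  rows <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    fit <- tryCatch(em_fit(data, specs[[i]], seed = seeds[i], ...),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      warning("model ", names(specs)[i], " failed to fit: ",
              conditionMessage(fit), call. = FALSE)
      rows[[i]] <- tibble::tibble(
        model = names(specs)[i],
        n_params = length(parameter_names(specs[[i]])),
        ibic = NA_real_, mean_choice_prob = NA_real_, converged = FALSE,
        failed = TRUE)
      next
    }
    fits[[i]] <- fit
    rows[[i]] <- tibble::tibble(
      model = names(specs)[i], n_params = length(parameter_names(specs[[i]])),
      ibic = fit$ibic, mean_choice_prob = fit$mean_choice_prob,
      converged = fit$converged, failed = FALSE)
  }
  names(fits) <- names(specs)
  out <- dplyr::bind_rows(rows)
  out <- dplyr::arrange(out, is.na(.data$ibic), .data$ibic)
  out$delta_ibic <- out$ibic - min(out$ibic, na.rm = TRUE)
  out <- dplyr::relocate(out, "delta_ibic", .after = "ibic")
  structure(out, fits = fits,
            class = c("gng_model_comparison", class(out)))
}

#' Best model of a comparison
#'
#' @param comparison A [compare_models()] table.
#' @return The canonical name of the lowest-iBIC model.
#' @export
best_model <- function(comparison) {
  stopifnot(inherits(comparison, "gng_model_comparison"))
  comparison$model[which.min(comparison$ibic)]
}
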