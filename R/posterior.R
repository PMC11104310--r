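#' Posterior-predictive learning curves
#'
#' Simulates `n_sims` replicate sessions per subject and administration at
#' each subject's MAP parameters, and aggregates go-rates by condition and
#' within-condition trial position, pooled over subjects, administrations
#' and simulations. Observed curves from the fitted data are aligned the
#' same way, and the agreement is summarized by the mean absolute
#' deviation (MAD) per condition.
#'
#' @param fit A [em_fit()] result.
#' @param data The cohort trial tibble the model was fitted to.
#' @param n_sims Simulated sessions per subject x administration.
#' @param rule The [outcome_rule()] used to simulate feedback.
#' @param seed Optional seed.
#' @param bin_width Trial-position bin width for the curves (default 1).
#' @return A list of class `"gng_posterior_predictive"`: `curves` (tibble
#'   with `condition`, `bin`, `observed_go_rate`, `predicted_go_rate`) and
#'   `mad` (tibble with per-condition mean absolute deviation).
#' @export
posterior_predictive <- function(fit, data, n_sims = 100,
                                 rule = outcome_rule(), seed = NULL,
                                 bin_width = 1) {
  spec <- fit$spec
  admins <- sort(unique(data$administration))
  n_per_condition <- max(condition_position(data)$position)
  sims <- with_seed(seed, {
    sim_seeds <- sample.int(.Machine$integer.max, length(fit$subject_fits))
    purrr::imap(fit$subject_fits, function(sf, sid) {
      with_seed(sim_seeds[match(sid, names(fit$subject_fits))] %% 2147483646L, {
        purrr::map(seq_len(n_sims), function(k) {
          tr <- simulate_agent_trials(sf$par_natural, spec,
                                      n_administrations = max(admins),
                                      n_per_condition = n_per_condition,
                                      rule = rule, subject_id = sid)
          tr$sim <- k
          tr
        }) |> dplyr::bind_rows()
      })
    }) |> dplyr::bind_rows()
  })
  obs <- curve_from_trials(data, bin_width) |>
    dplyr::rename(observed_go_rate = "go_rate")
  pred <- curve_from_trials(sims, bin_width) |>
    dplyr::rename(predicted_go_rate = "go_rate")
  curves <- dplyr::inner_join(obs, pred, by = c("condition", "bin"))
  mad <- curves |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      mad = mean(abs(.data$observed_go_rate - .data$predicted_go_rate)),
      .groups = "drop")
  structure(list(curves = curves, mad = mad, n_sims = n_sims),
            class = "gng_posterior_predictive")
}

# Within-condition trial position (1st, 2nd, ... presentation of each
# stimulus inside an administration; simulation replicates, when tagged
# with a `sim` column, are kept separate).
condition_position <- function(data) {
  grp <- intersect(c("sim", "subject_id", "administration", "condition"),
                   names(data))
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::arrange(.data$trial_index, .by_group = TRUE) |>
    dplyr::mutate(position = dplyr::row_number()) |>
    dplyr::ungroup()
}

curve_from_trials <- function(data, bin_width = 1) {
  condition_position(data) |>
    dplyr::mutate(bin = (.data$position - 1) %/% bin_width + 1) |>
    dplyr::group_by(.data$condition, .data$bin) |>
    dplyr::summarise(go_rate = mean(.data$action == "go"), .groups = "drop")
}

#' @export
print.gng_posterior_predictive <- function(x, ...) {
  cat("<gng_posterior_predictive>", x$n_sims, "simulations/subject\n")
  print(x$mad)
  invisible(x)
}
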