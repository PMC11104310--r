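#' Accuracy, RT and miss summaries by condition
#'
#' Accuracy is the fraction of trials on which the subject produced the
#' condition's correct action; a missed response counts as a nogo choice.
#' Mean RT is computed over go trials with a recorded response time.
#' Absent condition cells are kept as explicit rows with `NA` accuracy and
#' `n = 0` rather than silently dropped.
#'
#' @param data Trial tibble with `subject_id`, `administration`,
#'   `condition`, `action` and optionally `rt`.
#' @return A tibble with one row per subject x administration x condition:
#'   `accuracy`, `n`, `mean_rt`, `missed_rate`.
#' @export
accuracy_by_condition <- function(data) {
  if (!"rt" %in% names(data)) data$rt <- NA_real_
  conds <- gng_conditions()
  out <- data |>
    dplyr::left_join(conds[, c("condition", "correct_action")],
                     by = "condition") |>
    dplyr::mutate(
      effective_action = ifelse(.data$action == "missed", "nogo",
                                .data$action),
      correct = .data$effective_action == .data$correct_action) |>
    dplyr::group_by(.data$subject_id, .data$administration,
                    .data$condition) |>
    dplyr::summarise(
      accuracy = mean(.data$correct),
      n = dplyr::n(),
      mean_rt = mean(.data$rt[.data$action == "go"], na.rm = TRUE),
      missed_rate = mean(.data$action == "missed"),
      .groups = "drop") |>
    dplyr::mutate(mean_rt = ifelse(is.nan(.data$mean_rt), NA_real_,
                                   .data$mean_rt))
  out |>
    tidyr::complete(.data$subject_id, .data$administration,
                    condition = conds$condition,
                    fill = list(n = 0L)) |>
    dplyr::mutate(condition = as.character(.data$condition))
}

#' Per-subject Pavlovian bias indices
#'
#' The appetitive bias contrasts Pavlovian-congruent and incongruent
#' learning in the win domain, `acc(go_win) - acc(nogo_win)`; the aversive
#' bias does the same in the loss domain,
#' `acc(nogo_avoid) - acc(go_avoid)`. Positive values indicate a Pavlovian
#' influence. Accuracies are averaged over administrations first unless
#' `by_administration = TRUE`.
#'
#' @param summary An [accuracy_by_condition()] table.
#' @param by_administration Keep administrations separate?
#' @return A tibble with `subject_id` (and `administration`),
#'   `appetitive_bias`, `aversive_bias`, each in `[-1, 1]` (`NA` when a
#'   required cell is missing).
#' @export
pavlovian_bias_index <- function(summary, by_administration = FALSE) {
  grp <- if (by_administration) c("subject_id", "administration") else
    "subject_id"
  summary |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(grp, "condition")))) |>
    dplyr::summarise(accuracy = mean(.data$accuracy, na.rm = FALSE),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "accuracy") |>
    dplyr::mutate(
      appetitive_bias = .data$go_win - .data$nogo_win,
      aversive_bias = .data$nogo_avoid - .data$go_avoid) |>
    dplyr::select(dplyr::all_of(grp), "appetitive_bias", "aversive_bias")
}

congruency_means <- function(summary) {
  conds <- gng_conditions()
  summary |>
    dplyr::left_join(conds[, c("condition", "congruent")], by = "condition") |>
    dplyr::group_by(.data$subject_id, .data$congruent) |>
    dplyr::summarise(accuracy = mean(.data$accuracy, na.rm = TRUE),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "congruent", values_from = "accuracy",
                       names_prefix = "congruent_")
}

#' Paired t-test of congruent vs incongruent accuracy
#'
#' Congruent conditions are go-to-win and nogo-to-avoid; incongruent are
#' nogo-to-win and go-to-avoid. Subject means are compared with a paired t
#' (df = n - 1).
#'
#' @param summary An [accuracy_by_condition()] table.
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `mean_diff`,
#'   `n`, `degenerate` (TRUE when the paired differences have zero
#'   variance, in which case the test statistics are `NA`).
#' @export
congruency_ttest <- function(summary) {
  cm <- congruency_means(summary)
  cm <- cm[complete.cases(cm), ]
  if (nrow(cm) < 3) stop("need at least 3 subjects", call. = FALSE)
  d <- cm$congruent_TRUE - cm$congruent_FALSE
  if (sd(d) < 1e-12) {
    return(tibble::tibble(statistic = NA_real_, df = length(d) - 1,
                          p_value = NA_real_, mean_diff = mean(d),
                          n = length(d), degenerate = TRUE))
  }
  tt <- t.test(cm$congruent_TRUE, cm$congruent_FALSE, paired = TRUE)
  tibble::tibble(statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, mean_diff = mean(d), n = length(d),
                 degenerate = FALSE)
}

#' Two-way repeated-measures ANOVA on condition accuracy
#'
#' Action (go/nogo) x valence (win/loss) repeated-measures ANOVA on the
#' per-subject condition accuracies. With single-df factors each F equals
#' the squared paired t on the corresponding marginal means; this identity
#' is checked internally and returned.
#'
#' @param summary An [accuracy_by_condition()] table.
#' @return A tibble with one row per effect (`action`, `valence`,
#'   `action:valence`): `df1`, `df2`, `F`, `p_value`, plus the matching
#'   squared paired-t statistic `t_squared`.
#' @export
rm_anova_2x2 <- function(summary) {
  conds <- gng_conditions()
  cells <- summary |>
    dplyr::left_join(conds[, c("condition", "valence", "correct_action")],
                     by = "condition") |>
    dplyr::group_by(.data$subject_id, action = .data$correct_action,
                    valence = .data$valence) |>
    dplyr::summarise(accuracy = mean(.data$accuracy, na.rm = TRUE),
                     .groups = "drop")
  complete_subj <- cells |>
    dplyr::filter(is.finite(.data$accuracy)) |>
    dplyr::count(.data$subject_id) |>
    dplyr::filter(.data$n == 4)
  dropped <- setdiff(unique(cells$subject_id), complete_subj$subject_id)
  if (length(dropped)) {
    warning("excluding subject(s) with incomplete 2x2 cells: ",
            paste(dropped, collapse = ", "), call. = FALSE)
    cells <- dplyr::filter(cells,
                           .data$subject_id %in% complete_subj$subject_id)
  }
  cells <- dplyr::mutate(cells,
                         subject_id = factor(.data$subject_id),
                         action = factor(.data$action),
                         valence = factor(.data$valence))
  fit <- aov(accuracy ~ action * valence +
               Error(subject_id / (action * valence)), data = cells)
  sm <- summary(fit)
  pull_effect <- function(stratum, effect) {
    tab <- sm[[stratum]][[1]]
    row <- trimws(rownames(tab)) == effect
    tibble::tibble(effect = effect, df1 = tab$Df[row],
                   df2 = tab$Df[trimws(rownames(tab)) == "Residuals"],
                   F = tab$`F value`[row], p_value = tab$`Pr(>F)`[row])
  }
  out <- dplyr::bind_rows(
    pull_effect("Error: subject_id:action", "action"),
    pull_effect("Error: subject_id:valence", "valence"),
    pull_effect("Error: subject_id:action:valence", "action:valence"))
  # single-df identity: F(main or interaction) = paired-t^2 on a contrast
  wide <- cells |>
    tidyr::pivot_wider(names_from = c("action", "valence"),
                       values_from = "accuracy")
  tsq <- function(x, y) {
    d <- x - y
    if (sd(d) < 1e-14) return(NA_real_)
    (mean(d) / (sd(d) / sqrt(length(d))))^2
  }
  out$t_squared <- c(
    tsq((wide$go_win + wide$go_loss) / 2, (wide$nogo_win + wide$nogo_loss) / 2),
    tsq((wide$go_win + wide$nogo_win) / 2, (wide$go_loss + wide$nogo_loss) / 2),
    tsq((wide$go_win + wide$nogo_loss) / 2, (wide$nogo_win + wide$go_loss) / 2))
  out
}

#' Binned learning curves
#'
#' Go-rate by condition and within-condition trial bin. A trailing bin
#' with fewer than `bin_size` trials is retained and flagged `partial`.
#'
#' @param data Trial tibble.
#' @param bin_size Trials per bin (default 10).
#' @param by_administration Keep administrations separate?
#' @return A tibble with `condition`, `bin`, `go_rate`, `n_trials`,
#'   `partial` (and `administration` if requested).
#' @export
binned_learning_curves <- function(data, bin_size = 10,
                                   by_administration = FALSE) {
  if (bin_size < 1) stop("`bin_size` must be >= 1", call. = FALSE)
  grp <- c(if (by_administration) "administration", "condition", "bin")
  pos <- condition_position(data)
  n_pos <- max(pos$position)
  full_bins <- n_pos %/% bin_size
  pos |>
    dplyr::mutate(bin = (.data$position - 1) %/% bin_size + 1) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(go_rate = mean(.data$action == "go"),
                     n_trials = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(partial = .data$bin > full_bins)
}

#' Per-subject reaction-time summary
#'
#' Mean RT over go trials with a recorded response time, and the
#' proportion of trials missing the response deadline (flagged `missed`
#' actions, or recorded RTs exceeding the deadline).
#'
#' @param data Trial tibble.
#' @param deadline Response deadline in seconds (default 1.5).
#' @return A tibble with `subject_id`, `mean_go_rt`, `miss_rate`,
#'   `rt_available`.
#' @export
rt_summary <- function(data, deadline = 1.5) {
  if (!"rt" %in% names(data)) data$rt <- NA_real_
  data |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      mean_go_rt = mean(.data$rt[.data$action == "go"], na.rm = TRUE),
      miss_rate = mean(.data$action == "missed" |
                         (!is.na(.data$rt) & .data$rt > deadline)),
      rt_available = any(!is.na(.data$rt)),
      .groups = "drop") |>
    dplyr::mutate(mean_go_rt = ifelse(.data$rt_available, .data$mean_go_rt,
                                      NA_real_))
}

#' Cohen's d for paired pre/post change
#'
#' Reports the effect size of a pre-to-post change under the two common
#' conventions — mean change divided by the SD of the change scores, and
#' mean change divided by the pooled pre/post SD — which can differ
#' substantially when pre and post scores are correlated.
#'
#' @param pre,post Paired score vectors.
#' @return A tibble with `convention` (`"change_sd"`, `"pooled_sd"`), `d`,
#'   `mean_change`, `sd_used`, `degenerate` (TRUE when the relevant SD is
#'   zero).
#' @export
#' @examples
#' cohens_d_change(pre = c(4, 5, 6, 7), post = c(3, 3, 3, 3))
cohens_d_change <- function(pre, post) {
  stopifnot(length(pre) == length(post))
  ok <- complete.cases(pre, post)
  pre <- pre[ok]; post <- post[ok]
  change <- pre - post
  sd_change <- sd(change)
  sd_pooled <- sqrt((var(pre) + var(post)) / 2)
  mk <- function(conv, s) {
    d <- if (s > 0) mean(change) / s else if (mean(change) == 0) 0 else
      NA_real_
    tibble::tibble(convention = conv, d = d, mean_change = mean(change),
                   sd_used = s, degenerate = s <= 0 && mean(change) != 0)
  }
  dplyr::bind_rows(mk("change_sd", sd_change), mk("pooled_sd", sd_pooled))
}
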