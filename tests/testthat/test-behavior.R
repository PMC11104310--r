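toy_trials <- function(actions_by_condition, subject_id = "s01",
                       administration = 1L) {
  # actions_by_condition: named list condition -> vector of actions
  purrr::imap(actions_by_condition, function(acts, cond) {
    tibble::tibble(subject_id = subject_id,
                   administration = administration,
                   condition = cond, action = acts,
                   outcome = 0L, rt = NA_real_)
  }) |>
    dplyr::bind_rows() |>
    dplyr::mutate(trial_index = dplyr::row_number())
}

test_that("accuracy counts correct actions, with missed as nogo", {
  d <- toy_trials(list(
    go_win = rep("go", 4),                      # all correct
    nogo_win = c("go", "nogo", "go", "nogo"),   # alternating: 0.5
    go_avoid = c("go", "go", "missed", "nogo"), # missed counts as nogo: 0.5
    nogo_avoid = rep("missed", 4)))             # missed = nogo = correct
  acc <- accuracy_by_condition(d)
  get <- function(cond) acc$accuracy[acc$condition == cond]
  expect_equal(get("go_win"), 1)
  expect_equal(get("nogo_win"), 0.5)
  expect_equal(get("go_avoid"), 0.5)
  expect_equal(get("nogo_avoid"), 1)
  expect_equal(acc$missed_rate[acc$condition == "nogo_avoid"], 1)
})

test_that("absent condition cells are flagged rather than zero", {
  d <- toy_trials(list(go_win = rep("go", 4)))
  acc <- accuracy_by_condition(d)
  expect_equal(nrow(acc), 4)
  expect_true(is.na(acc$accuracy[acc$condition == "nogo_win"]))
  expect_equal(acc$n[acc$condition == "nogo_win"], 0L)
  # and a missing cell propagates to an undefined bias index
  bias <- pavlovian_bias_index(acc)
  expect_true(is.na(bias$appetitive_bias))
})

test_that("Pavlovian bias indices are the stated accuracy differences", {
  acc <- tibble::tibble(
    subject_id = "s01", administration = 1L,
    condition = c("go_win", "nogo_win", "nogo_avoid", "go_avoid"),
    accuracy = c(0.9, 0.5, 0.8, 0.6), n = 10L, mean_rt = NA_real_,
    missed_rate = 0)
  bias <- pavlovian_bias_index(acc)
  expect_equal(bias$appetitive_bias, 0.4)
  expect_equal(bias$aversive_bias, 0.2)
  acc$accuracy <- 0.75
  bias0 <- pavlovian_bias_index(acc)
  expect_equal(bias0$appetitive_bias, 0)
  expect_equal(bias0$aversive_bias, 0)
})

test_that("zero-Pavlovian agents show no bias on average", {
  trials <- sim_pav_cohort(0, 0, n_subjects = 40, n_per_condition = 15,
                           seed = 3, b = 0)
  bias <- pavlovian_bias_index(accuracy_by_condition(trials))
  expect_lt(abs(mean(bias$appetitive_bias)), 0.06)
  expect_lt(abs(mean(bias$aversive_bias)), 0.06)
})

test_that("strong Pavlovian agents favour go_win over nogo_win", {
  wins <- vapply(1:60, function(k) {
    trials <- sim_pav_cohort(2, 2, n_subjects = 1, n_per_condition = 25,
                             seed = 500 + k)
    acc <- accuracy_by_condition(trials)
    acc$accuracy[acc$condition == "go_win"] >
      acc$accuracy[acc$condition == "nogo_win"]
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("the congruency t-test matches the textbook paired-t formula", {
  # 4 subjects with known congruent-incongruent differences
  diffs <- c(0.1, 0.2, 0.1, 0.2)
  base <- c(0.6, 0.65, 0.7, 0.62)
  acc <- purrr::map(1:4, function(i) {
    tibble::tibble(
      subject_id = sprintf("s%02d", i), administration = 1L,
      condition = c("go_win", "nogo_avoid", "nogo_win", "go_avoid"),
      accuracy = c(base[i] + diffs[i], base[i] + diffs[i], base[i], base[i]),
      n = 10L, mean_rt = NA_real_, missed_rate = 0)
  }) |> dplyr::bind_rows()
  tt <- congruency_ttest(acc)
  t_oracle <- mean(diffs) / (sd(diffs) / sqrt(4))
  expect_equal(tt$statistic, t_oracle, tolerance = 1e-10)
  expect_equal(tt$df, 3)
  # degenerate when the differences have no variance
  acc_flat <- dplyr::mutate(acc, accuracy = 0.7)
  expect_true(congruency_ttest(acc_flat)$degenerate)
  expect_error(congruency_ttest(acc[acc$subject_id %in% c("s01", "s02"), ]),
               "at least 3")
})

test_that("strong Pavlovian cohorts yield significant congruency effects", {
  sig <- vapply(1:20, function(k) {
    trials <- sim_pav_cohort(1.5, 1.5, n_subjects = 12,
                             n_per_condition = 20, seed = 900 + k)
    congruency_ttest(accuracy_by_condition(trials))$p_value < 0.05
  }, logical(1))
  expect_gte(mean(sig), 0.8)
})

test_that("the repeated-measures ANOVA matches a sums-of-squares oracle", {
  # small worked dataset, 3 subjects x 4 cells
  cells <- tidyr::expand_grid(
    subject_id = c("s1", "s2", "s3"),
    condition = c("go_win", "nogo_win", "go_avoid", "nogo_avoid"))
  cells$accuracy <- c(0.9, 0.5, 0.7, 0.8,
                      0.85, 0.55, 0.65, 0.9,
                      0.95, 0.4, 0.6, 0.7)
  acc <- dplyr::mutate(cells, administration = 1L, n = 10L,
                       mean_rt = NA_real_, missed_rate = 0)
  out <- rm_anova_2x2(acc)
  # independent oracle: full two-way repeated-measures decomposition
  m <- matrix(acc$accuracy, nrow = 3, byrow = TRUE,
              dimnames = list(NULL, c("go_win", "nogo_win", "go_avoid",
                                      "nogo_avoid")))
  go_m <- (m[, "go_win"] + m[, "go_avoid"]) / 2
  ng_m <- (m[, "nogo_win"] + m[, "nogo_avoid"]) / 2
  t_action <- mean(go_m - ng_m) / (sd(go_m - ng_m) / sqrt(3))
  expect_equal(out$F[out$effect == "action"], t_action^2, tolerance = 1e-10)
  win_m <- (m[, "go_win"] + m[, "nogo_win"]) / 2
  ls_m <- (m[, "go_avoid"] + m[, "nogo_avoid"]) / 2
  t_val <- mean(win_m - ls_m) / (sd(win_m - ls_m) / sqrt(3))
  expect_equal(out$F[out$effect == "valence"], t_val^2, tolerance = 1e-10)
  inter <- (m[, "go_win"] - m[, "go_avoid"]) -
    (m[, "nogo_win"] - m[, "nogo_avoid"])
  t_int <- mean(inter) / (sd(inter) / sqrt(3))
  # interaction contrast t^2 equals F for the 1-df interaction (the
  # contrast is half the interaction effect; t^2 is scale-invariant)
  expect_equal(out$F[out$effect == "action:valence"], t_int^2,
               tolerance = 1e-10)
  expect_equal(out$df1, rep(1, 3))
  expect_equal(out$df2, rep(2, 3))
})

test_that("the 1-df F = t^2 identity holds on simulated cohorts", {
  trials <- sim_pav_cohort(1, 0.5, n_subjects = 8, n_per_condition = 15,
                           seed = 77)
  out <- rm_anova_2x2(accuracy_by_condition(trials))
  expect_equal(out$F, out$t_squared, tolerance = 1e-10)
})

test_that("binned learning curves have the right bins and flags", {
  d <- toy_trials(list(go_win = rep("go", 60)))
  curves <- binned_learning_curves(d, 10)
  gw <- curves[curves$condition == "go_win", ]
  expect_equal(nrow(gw), 6)
  expect_true(all(gw$go_rate == 1))
  expect_false(any(gw$partial))
  d13 <- toy_trials(list(go_win = rep(c("go", "nogo"), length.out = 13)))
  c13 <- binned_learning_curves(d13, 10)
  expect_equal(c13$n_trials, c(10L, 3L))
  expect_equal(c13$partial, c(FALSE, TRUE))
  expect_error(binned_learning_curves(d, 0), "bin_size")
})

test_that("learning agents improve their go_win go-rate over bins", {
  rhos <- vapply(1:50, function(k) {
    trials <- sim_pav_cohort(0.5, 0.5, n_subjects = 2,
                             n_per_condition = 30, seed = 1500 + k)
    curves <- binned_learning_curves(trials, 10)
    gw <- curves[curves$condition == "go_win", ]
    suppressWarnings(stats::cor(gw$bin, gw$go_rate, method = "spearman"))
  }, numeric(1))
  expect_gt(mean(rhos, na.rm = TRUE), 0)
})

test_that("RT summaries respect the deadline and availability", {
  d <- tibble::tibble(
    subject_id = "s01", administration = 1L, trial_index = 1:4,
    condition = "go_win", action = c("go", "go", "go", "go"),
    outcome = 1L, rt = c(0.5, 0.5, 0.5, 0.5))
  out <- rt_summary(d)
  expect_equal(out$mean_go_rt, 0.5)
  expect_equal(out$miss_rate, 0)
  d2 <- dplyr::mutate(d, rt = c(0.5, 0.5, 1.6, 1.7))
  expect_equal(rt_summary(d2)$miss_rate, 0.5)
  d3 <- dplyr::mutate(d, rt = NA_real_)
  out3 <- rt_summary(d3)
  expect_false(out3$rt_available)
  expect_true(is.na(out3$mean_go_rt))
})

test_that("Cohen's d reports both conventions and flags degeneracy", {
  same <- cohens_d_change(c(10, 12, 14), c(10, 12, 14))
  expect_equal(same$d[same$convention == "change_sd"], 0)
  const <- cohens_d_change(c(20, 21, 22, 23), c(10, 11, 12, 13))
  expect_true(const$degenerate[const$convention == "change_sd"])
  expect_true(is.na(const$d[const$convention == "change_sd"]))
  hand <- cohens_d_change(c(11, 12, 13, 14), c(10, 10, 10, 10))
  expect_equal(hand$d[hand$convention == "change_sd"],
               2.5 / sd(c(1, 2, 3, 4)), tolerance = 1e-10)
  expect_equal(hand$d[hand$convention == "pooled_sd"],
               2.5 / sqrt((var(c(11, 12, 13, 14)) + 0) / 2),
               tolerance = 1e-10)
})
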