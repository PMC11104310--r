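#' Generate a synthetic Go/No-Go task cohort with known ground truth
#'
#' Subject parameters are drawn from a Gaussian prior on the transformed
#' scale ([default_task_prior()] unless overridden) and each subject plays
#' `n_administrations` sessions of the task, with the session-varying
#' Pavlovian weights switching at administrations 3 and 4 as in the study
#' design (task administrations at weeks 0, 1, 4, 7 and 9). Go-trial
#' response times are drawn from a lognormal well inside the 1.5 s
#' deadline; a fraction `p_miss` of go responses can be converted to
#' flagged misses (default 0).
#'
#' @param n_subjects Number of subjects (default 12).
#' @param spec A [model_spec()] (default: the session-varying
#'   dual-Pavlovian model).
#' @param prior A [gng_prior()] to draw subjects from.
#' @param n_administrations,n_per_condition Task dimensions (defaults 5
#'   and 60: five administrations of 240 trials).
#' @param rule An [outcome_rule()]. The generator defaults to the
#'   `"conventional"` variant (win conditions deliver reward or nothing),
#'   which matches the learning model's value structure and reproduces the
#'   canonical accuracy ordering (congruent conditions easiest,
#'   no-go-to-win hardest); under the `"paper_text"` variant the
#'   wrong-action losses make no-go-to-win easy instead.
#' @param p_miss Probability that a go response becomes a flagged missed
#'   response (treated as nogo for learning downstream).
#' @param seed Optional seed; the cohort is bit-reproducible given it.
#' @return A list of class `"gng_cohort"`: `trials` (trial tibble),
#'   `truth` (per-subject natural-scale parameters plus the transformed
#'   draws), `prior`, `spec`, `settings`.
#' @export
gen_task_cohort <- function(n_subjects = 12,
                            spec = model_spec("dual", session_varying = TRUE),
                            prior = default_task_prior(spec),
                            n_administrations = 5, n_per_condition = 60,
                            rule = outcome_rule(variant = "conventional"),
                            p_miss = 0, seed = NULL) {
  with_seed(seed, {
    draws <- draw_from_prior(prior, n_subjects)
    ids <- sprintf("s%02d", seq_len(n_subjects))
    truth <- purrr::map(seq_len(n_subjects), function(i) {
      theta <- setNames(draws[i, ], prior$parameter)
      nat <- untransform_params(theta, spec)
      tibble::tibble(subject_id = ids[i], parameter = prior$parameter,
                     transformed = unname(theta), value = unname(nat))
    }) |> dplyr::bind_rows()
    trials <- purrr::map(seq_len(n_subjects), function(i) {
      nat <- truth$value[truth$subject_id == ids[i]]
      names(nat) <- prior$parameter
      tr <- simulate_agent_trials(nat, spec, n_administrations,
                                  n_per_condition, rule,
                                  subject_id = ids[i])
      tr$rt <- ifelse(tr$action == "go",
                      pmin(exp(rnorm(nrow(tr), log(0.55), 0.2)), 1.45),
                      NA_real_)
      if (p_miss > 0) {
        miss <- tr$action == "go" & runif(nrow(tr)) < p_miss
        tr$action[miss] <- "missed"
        tr$rt[miss] <- 1.5 + runif(sum(miss), 0, 0.5)
      }
      tr
    }) |> dplyr::bind_rows()
    structure(
      list(trials = trials, truth = truth, prior = prior, spec = spec,
           settings = list(n_subjects = n_subjects,
                           n_administrations = n_administrations,
                           n_per_condition = n_per_condition,
                           dominant_prob = attr(rule, "dominant_prob"),
                           variant = attr(rule, "variant"),
                           p_miss = p_miss, seed = seed)),
      class = "gng_cohort")
  })
}

#' True per-subject parameter table of a synthetic cohort, wide format
#'
#' @param cohort A [gen_task_cohort()] result.
#' @return Tibble with one row per subject and one column per parameter
#'   (natural scale), plus `delta_pi_app` / `delta_pi_av` when the
#'   generating model is session-varying.
#' @export
cohort_truth_wide <- function(cohort) {
  out <- cohort$truth |>
    dplyr::select("subject_id", "parameter", "value") |>
    tidyr::pivot_wider(names_from = "parameter", values_from = "value")
  if (cohort$spec$session_varying) {
    out <- dplyr::mutate(out,
                         delta_pi_app = .data$pi_app_post - .data$pi_app,
                         delta_pi_av = .data$pi_av_post - .data$pi_av)
  }
  out
}

activity_categories <- function() {
  c("emotional", "mental", "physical", "pleasure", "sensory", "social",
    "spiritual")
}

clip_rating <- function(x, scale_max) pmin(pmax(round(x), 0), scale_max)

#' Generate synthetic GOAL-form activity diaries
#'
#' Each agent holds internal reward and punishment expectations `R_a`,
#' `P_a` for a menu of activities (two per category across the seven
#' activity categories). Each day it performs the planned activity,
#' reports its predictions (`R_pre`, `P_pre` — the internal value plus
#' reporting noise, rounded and clipped to the 0..`scale_max` integer
#' scale), experiences reward and punishment drawn around the activity's
#' latent true values, and updates its expectation by a prediction error
#' anchored on the stated prediction:
#' `R_a <- R_pre + rho * (r - R_pre)` (punishment analogous), where `rho`
#' is the subject's update rate. The post-completion predictions
#' `R_post1`, `P_post1` are noisy reports of the updated values. The next
#' day's activity repeats the current one with probability
#' `plogis(repeat_intercept + repeat_reward * r + repeat_punish * p)`,
#' otherwise a different activity is drawn uniformly.
#'
#' Per-subject update rates are drawn from a normal with mean
#' `update_rate_mean` and SD `update_rate_sd`, truncated to (0.02, 0.98);
#' if `item_change` scores are supplied with nonzero `item_coupling`,
#' the subject's rate is `update_rate_mean + item_coupling * item_change`
#' instead (plus the SD noise), which is the ground truth for the
#' anhedonia-interaction analyses.
#'
#' @param n_subjects,n_days Cohort dimensions (defaults 12 subjects, 56
#'   diary days).
#' @param n_activities Size of the activity menu (default 14).
#' @param update_rate_mean,update_rate_sd Distribution of the true update
#'   rate (defaults 0.7 and 0.1).
#' @param rating_noise_sd Reporting noise on every recorded rating
#'   (default 0.5).
#' @param experience_noise_sd Spread of experienced outcomes around the
#'   activity's latent value (default 1.5).
#' @param scale_max Upper end of the integer rating scale (default 10).
#' @param repeat_intercept,repeat_reward,repeat_punish Logistic
#'   coefficients of the next-day repetition rule (defaults -2.5, 0.4,
#'   0.1).
#' @param item_change Optional tibble (`subject_id` = `s01`..., or plain
#'   numeric vector of length `n_subjects`) of anhedonia-item change
#'   scores.
#' @param item_coupling Coupling of the update rate to `item_change`
#'   (default 0).
#' @param seed Optional seed.
#' @return A list of class `"goal_cohort"`: `entries` (diary tibble with
#'   `subject_id`, `day`, `activity_id`, `category`, `R_pre`, `P_pre`,
#'   `r`, `p`, `R_post1`, `P_post1`) and `truth` (per-subject update
#'   rates, repetition coefficients, settings).
#' @export
gen_goal_cohort <- function(n_subjects = 12, n_days = 56, n_activities = 14,
                            update_rate_mean = 0.7, update_rate_sd = 0.1,
                            rating_noise_sd = 0.5, experience_noise_sd = 1.5,
                            scale_max = 10, repeat_intercept = -2.5,
                            repeat_reward = 0.4, repeat_punish = 0.1,
                            item_change = NULL, item_coupling = 0,
                            seed = NULL) {
  ids <- sprintf("s%02d", seq_len(n_subjects))
  ic <- if (is.null(item_change)) {
    setNames(rep(0, n_subjects), ids)
  } else if (is.data.frame(item_change)) {
    setNames(item_change$item_change, item_change$subject_id)[ids]
  } else {
    setNames(rep_len(item_change, n_subjects), ids)
  }
  cats <- rep_len(activity_categories(), n_activities)
  acts <- sprintf("a%02d", seq_len(n_activities))
  with_seed(seed, {
    rho <- pmin(pmax(update_rate_mean + item_coupling * ic +
                       rnorm(n_subjects, 0, update_rate_sd), 0.02), 0.98)
    entries <- purrr::map(seq_len(n_subjects), function(i) {
      true_r <- runif(n_activities, 2, 8)
      true_p <- runif(n_activities, 1, 6)
      R <- rep(scale_max / 2, n_activities)
      P <- rep(scale_max / 2, n_activities)
      cur <- sample.int(n_activities, 1)
      rows <- vector("list", n_days)
      for (d in seq_len(n_days)) {
        R_pre <- clip_rating(R[cur] + rnorm(1, 0, rating_noise_sd), scale_max)
        P_pre <- clip_rating(P[cur] + rnorm(1, 0, rating_noise_sd), scale_max)
        r <- clip_rating(true_r[cur] + rnorm(1, 0, experience_noise_sd),
                         scale_max)
        p <- clip_rating(true_p[cur] + rnorm(1, 0, experience_noise_sd),
                         scale_max)
        R[cur] <- R_pre + rho[i] * (r - R_pre)
        P[cur] <- P_pre + rho[i] * (p - P_pre)
        R_post1 <- clip_rating(R[cur] + rnorm(1, 0, rating_noise_sd),
                               scale_max)
        P_post1 <- clip_rating(P[cur] + rnorm(1, 0, rating_noise_sd),
                               scale_max)
        rows[[d]] <- tibble::tibble(
          subject_id = ids[i], day = d, activity_id = acts[cur],
          category = cats[cur], R_pre = R_pre, P_pre = P_pre, r = r, p = p,
          R_post1 = R_post1, P_post1 = P_post1)
        p_rep <- plogis(repeat_intercept + repeat_reward * r +
                          repeat_punish * p)
        cur <- if (runif(1) < p_rep) cur else
          sample(setdiff(seq_len(n_activities), cur), 1)
      }
      dplyr::bind_rows(rows)
    }) |> dplyr::bind_rows()
    structure(
      list(entries = entries,
           truth = list(
             update_rates = tibble::tibble(subject_id = ids,
                                           update_rate = unname(rho),
                                           item_change = unname(ic)),
             repeat_coefficients = c(intercept = repeat_intercept,
                                     r = repeat_reward, p = repeat_punish),
             settings = list(n_subjects = n_subjects, n_days = n_days,
                             n_activities = n_activities,
                             update_rate_mean = update_rate_mean,
                             update_rate_sd = update_rate_sd,
                             rating_noise_sd = rating_noise_sd,
                             experience_noise_sd = experience_noise_sd,
                             scale_max = scale_max,
                             item_coupling = item_coupling, seed = seed))),
      class = "goal_cohort")
  })
}

#' Generate synthetic weekly symptom trajectories
#'
#' Weekly total depression scores follow the step-change structure of the
#' symptom regression: a subject-specific mean, fixed improvements after
#' the reward-focused (week `t3_week`) and avoidance-focused (week
#' `t7_week`) therapy phases, improvements proportional to the subject's
#' Pavlovian parameter changes, and Gaussian noise. Scores are rounded to
#' integers and clipped to the instrument range 0..84 when `noise_sd > 0`;
#' with `noise_sd = 0` the raw linear values are returned so the design is
#' exactly recoverable. Anhedonia items 19 and 21 (each 0..3) decline in
#' proportion to the subject's total-score trajectory with small
#' independent noise.
#'
#' @param n_subjects Number of subjects (default 12).
#' @param weeks Weeks of measurement (default 0:9).
#' @param weights Fixed-effect weights on `(step3, step7, app_change_x,
#'   av_change_x)`; default `c(-5, -4, -2, -2)`.
#' @param changes Optional tibble (`subject_id`, `delta_pi_app`,
#'   `delta_pi_av`); by default drawn N(0.5, 1) per subject, matching a
#'   therapy-driven increase in both Pavlovian weights.
#' @param intercept_mean,intercept_sd Subject-mean distribution (defaults
#'   34.5 and 8.5, a moderately depressed cohort).
#' @param noise_sd Residual SD (default 2).
#' @param t3_week,t7_week Phase-change weeks (defaults 4 and 7).
#' @param seed Optional seed.
#' @return A list of class `"symptom_cohort"`: `series` (tibble
#'   `subject_id`, `week`, `ids_total`, `item19`, `item21`) and `truth`
#'   (weights, changes, intercepts, settings).
#' @export
gen_symptom_cohort <- function(n_subjects = 12, weeks = 0:9,
                               weights = c(-5, -4, -2, -2), changes = NULL,
                               intercept_mean = 34.5, intercept_sd = 8.5,
                               noise_sd = 2, t3_week = 4, t7_week = 7,
                               seed = NULL) {
  stopifnot(length(weights) == 4)
  ids <- sprintf("s%02d", seq_len(n_subjects))
  with_seed(seed, {
    if (is.null(changes)) {
      changes <- tibble::tibble(subject_id = ids,
                                delta_pi_app = rnorm(n_subjects, 0.5, 1),
                                delta_pi_av = rnorm(n_subjects, 0.5, 1))
    }
    intercepts <- rnorm(n_subjects, intercept_mean, intercept_sd)
    series <- purrr::map(seq_len(n_subjects), function(i) {
      step3 <- as.numeric(weeks >= t3_week)
      step7 <- as.numeric(weeks >= t7_week)
      dpi <- changes[changes$subject_id == ids[i], ]
      mu <- intercepts[i] + weights[1] * step3 + weights[2] * step7 +
        weights[3] * dpi$delta_pi_app * step3 +
        weights[4] * dpi$delta_pi_av * step7
      y <- mu + rnorm(length(weeks), 0, noise_sd)
      if (noise_sd > 0) y <- pmin(pmax(round(y), 0), 84)
      frac <- y / max(intercepts[i], 1)
      tibble::tibble(
        subject_id = ids[i], week = as.integer(weeks), ids_total = y,
        item19 = pmin(pmax(round(3 * frac + rnorm(length(weeks), 0, 0.3)),
                           0), 3),
        item21 = pmin(pmax(round(3 * frac + rnorm(length(weeks), 0, 0.3)),
                           0), 3))
    }) |> dplyr::bind_rows()
    structure(
      list(series = series,
           truth = list(weights = setNames(weights,
                                           c("step3", "step7",
                                             "app_change_x", "av_change_x")),
                        changes = changes,
                        intercepts = tibble::tibble(subject_id = ids,
                                                    intercept = intercepts),
                        settings = list(weeks = weeks, noise_sd = noise_sd,
                                        t3_week = t3_week, t7_week = t7_week,
                                        seed = seed))),
      class = "symptom_cohort")
  })
}
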