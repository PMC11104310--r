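#' Build a generative agent for the model family
#'
#' Returns a stateful policy usable with [simulate_session()]: `act()`
#' samples action probabilities from the current learner state via
#' [action_values()] and [action_probabilities()], `update()` applies the
#' Rescorla-Wagner rule, and `reset()` zeroes the state at the start of an
#' administration (and records which administration is running, so the
#' session-varying Pavlovian weights switch at the right times).
#'
#' @param params Named natural-scale parameter vector.
#' @param spec A [model_spec()].
#' @return A list with functions `act(condition)`,
#'   `update(condition, action, outcome)`, `reset(administration)` and the
#'   stored `params` and `spec`.
#' @export
#' @examples
#' sp <- model_spec("none", has_noise = FALSE, has_bias = FALSE)
#' ag <- make_agent(c(alpha = 0.3, beta = 2), sp)
#' simulate_session(ag, generate_schedule(5, seed = 1), seed = 2)
make_agent <- function(params, spec) {
  params <- check_param_vector(params, parameter_names(spec))
  state <- learner_state()
  administration <- 1L
  list(
    act = function(condition) {
      v <- action_values(state, condition, params, spec, administration)
      xi <- par_slots(params, spec)[4]
      idx <- as_condition_index(condition)
      if (gng_conditions()$valence[idx] == "loss") {
        xi <- par_slots(params, spec)[10]
      }
      action_probabilities(v, xi)
    },
    update = function(condition, action, outcome) {
      state <<- update_state(state, condition, action, outcome, params, spec)
    },
    reset = function(adm) {
      state <<- learner_state()
      administration <<- as.integer(adm)
    },
    params = params,
    spec = spec
  )
}

#' Simulate a full multi-administration dataset for one agent (fast path)
#'
#' Equivalent to running [make_agent()] through [simulate_session()] for
#' each administration, but executed in compiled code. Used by the cohort
#' generator.
#'
#' @inheritParams make_agent
#' @param n_administrations Number of task administrations (default 5).
#' @param n_per_condition Trials per condition per administration.
#' @param rule An [outcome_rule()].
#' @param seed Optional seed (caller's RNG state restored).
#' @param subject_id Identifier stamped on the records.
#' @return A trial tibble with columns `subject_id`, `administration`,
#'   `trial_index`, `condition`, `action`, `outcome`, `rt`.
#' @export
simulate_agent_trials <- function(params, spec, n_administrations = 5,
                                  n_per_condition = 60,
                                  rule = outcome_rule(), seed = NULL,
                                  subject_id = "s01") {
  slots <- par_slots(params, spec)
  mats <- rule_matrices(rule)
  with_seed(seed, {
    admins <- lapply(seq_len(n_administrations), function(adm) {
      sched <- generate_schedule(n_per_condition)
      idx <- as_condition_index(sched$condition)
      win <- as.integer(gng_conditions()$valence[idx] == "win")
      sim <- cpp_simulate_admin(as.integer(idx), win, mats$go, mats$nogo,
                                slots, as.integer(adm))
      tibble::tibble(
        subject_id = subject_id,
        administration = as.integer(adm),
        trial_index = sched$trial_index,
        condition = sched$condition,
        action = ifelse(sim$action_go == 1L, "go", "nogo"),
        outcome = as.integer(sim$outcome),
        rt = NA_real_
      )
    })
    dplyr::bind_rows(admins)
  })
}
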