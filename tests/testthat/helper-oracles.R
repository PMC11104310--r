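# Hand-unrolled reference implementations, written independently of the
# package's likelihood path, used as oracles in the model tests.

# Condition layout mirrored by index: 1 go_win, 2 nogo_win, 3 go_avoid,
# 4 nogo_avoid. `p` is a plain list with alpha, beta, b, xi, pi_app,
# pi_av, pi_app_post, pi_av_post (use 0 / pre-values to neutralize).
oracle_nll <- function(cond, action_go, outcome, admin, p) {
  win <- c(TRUE, TRUE, FALSE, FALSE)
  Q <- matrix(0, nrow = 2, ncol = 4) # row 1 go, row 2 nogo
  V <- rep(0, 4)
  nll <- 0
  cur_admin <- -1L
  for (i in seq_along(cond)) {
    if (admin[i] != cur_admin) {
      cur_admin <- admin[i]
      Q[] <- 0
      V[] <- 0
    }
    s <- cond[i]
    pi_eff <- if (win[s]) {
      if (cur_admin >= 3) p$pi_app_post else p$pi_app
    } else {
      if (cur_admin >= 4) p$pi_av_post else p$pi_av
    }
    wgo <- Q[1, s] + p$b + pi_eff * V[s]
    wng <- Q[2, s]
    pgo <- exp(wgo) / (exp(wgo) + exp(wng)) * (1 - p$xi) + p$xi / 2
    pa <- if (action_go[i] == 1) pgo else 1 - pgo
    nll <- nll - log(pa)
    a <- if (action_go[i] == 1) 1 else 2
    Q[a, s] <- Q[a, s] + p$alpha * (p$beta * outcome[i] - Q[a, s])
    V[s] <- V[s] + p$alpha * (p$beta * outcome[i] - V[s])
  }
  nll
}

oracle_trials_tibble <- function(cond, action_go, outcome, admin) {
  lv <- c("go_win", "nogo_win", "go_avoid", "nogo_avoid")
  tibble::tibble(
    administration = as.integer(admin),
    trial_index = as.integer(stats::ave(admin, admin, FUN = seq_along)),
    condition = lv[cond],
    action = ifelse(action_go == 1, "go", "nogo"),
    outcome = as.integer(outcome))
}

random_full_params <- function() {
  list(alpha = runif(1, 0.05, 0.6), beta = runif(1, 0.5, 5),
       b = rnorm(1, 0, 0.5), xi = runif(1, 0.01, 0.3),
       pi_app = rnorm(1, 0.5, 0.7), pi_av = rnorm(1, 0.5, 0.7),
       pi_app_post = rnorm(1, 1, 0.7), pi_av_post = rnorm(1, 1, 0.7))
}

full_spec <- function() model_spec("dual", session_varying = TRUE)

as_named_params <- function(p, spec = full_spec()) {
  unlist(p)[parameter_names(spec)]
}

# Small simulated cohort shared by behavioural tests (built once per run).
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- gen_task_cohort(n_subjects = 6, n_administrations = 2,
                                n_per_condition = 20, seed = 424242)
    }
    cache
  }
})

# Quick strong/zero-Pavlovian agent cohorts for directional checks.
sim_pav_cohort <- function(pi_app, pi_av, n_subjects = 12,
                           n_per_condition = 30, seed = 1, b = 0.3,
                           rule = outcome_rule(variant = "conventional")) {
  sp <- model_spec("dual")
  purrr::map(seq_len(n_subjects), function(i) {
    simulate_agent_trials(
      c(alpha = 0.25, beta = 3, b = b, xi = 0.05,
        pi_app = pi_app, pi_av = pi_av),
      sp, n_administrations = 1, n_per_condition = n_per_condition,
      rule = rule, seed = seed * 1000 + i,
      subject_id = sprintf("s%02d", i))
  }) |> dplyr::bind_rows()
}
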