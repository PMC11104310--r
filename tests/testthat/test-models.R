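test_that("model specs derive parameter names and canonical names", {
  expect_equal(parameter_names(model_spec("none", has_noise = FALSE,
                                          has_bias = FALSE)),
               c("alpha", "beta"))
  expect_equal(parameter_names(full_spec()),
               c("alpha", "beta", "b", "xi", "pi_app", "pi_av",
                 "pi_app_post", "pi_av_post"))
  expect_equal(model_name(model_spec("single")), "RW+noise+bias+Pav")
  expect_error(model_spec("single", session_varying = TRUE), "dual")
  expect_equal(names(model_set()),
               c("RW", "RW+noise", "RW+noise+bias", "RW+noise+bias+Pav",
                 "RW+noise+bias+2Pav", "RW+noise+bias+2Pav+session"))
})

test_that("parameter transforms are exact inverses", {
  sp <- full_spec()
  expect_equal(transform_params(c(alpha = 0.5, beta = 1, b = 0.1, xi = 0.5,
                                  pi_app = 1, pi_av = -1, pi_app_post = 0,
                                  pi_av_post = 2), sp)[c("alpha", "beta")],
               c(alpha = 0, beta = 0))
  set.seed(11)
  for (k in 1:20) {
    theta <- rnorm(8, 0, 2)
    names(theta) <- parameter_names(sp)
    nat <- untransform_params(theta, sp)
    expect_true(nat[["alpha"]] > 0 && nat[["alpha"]] < 1)
    expect_true(nat[["beta"]] > 0)
    expect_equal(transform_params(nat, sp), theta, tolerance = 1e-10)
  }
  expect_error(transform_params(c(alpha = NA, beta = 1), model_spec(
    "none", has_noise = FALSE, has_bias = FALSE)), "finite")
})

test_that("effective Pavlovian weights switch at administrations 3 and 4", {
  sp <- full_spec()
  th <- c(alpha = 0.2, beta = 3, b = 0.3, xi = 0.05, pi_app = 0.5,
          pi_av = 0.6, pi_app_post = 1.2, pi_av_post = 1.4)
  expect_equal(effective_pavlovian(th, sp, 2), c(pi_app = 0.5, pi_av = 0.6))
  expect_equal(effective_pavlovian(th, sp, 3), c(pi_app = 1.2, pi_av = 0.6))
  expect_equal(effective_pavlovian(th, sp, 4), c(pi_app = 1.2, pi_av = 1.4))
  expect_equal(effective_pavlovian(th, sp, 5), c(pi_app = 1.2, pi_av = 1.4))
  # passthrough without session variation
  sp2 <- model_spec("dual")
  th2 <- th[parameter_names(sp2)]
  for (adm in 1:5) {
    expect_equal(effective_pavlovian(th2, sp2, adm),
                 c(pi_app = 0.5, pi_av = 0.6))
  }
  expect_error(effective_pavlovian(th, sp, 6), "1..5")
})

test_that("action values add bias and Pavlovian terms to go only", {
  sp <- model_spec("dual")
  th <- c(alpha = 0.2, beta = 3, b = 0.1, xi = 0, pi_app = 1, pi_av = 1)
  st <- learner_state()
  expect_equal(action_values(st, "go_win", th, sp), c(go = 0.1, nogo = 0))
  st$Q["go", 1] <- 0.2
  st$Q["nogo", 1] <- -0.3
  st$V[1] <- 0.5
  expect_equal(action_values(st, "go_win", th, sp),
               c(go = 0.2 + 0.1 + 1 * 0.5, nogo = -0.3))
  # aversive weight applies to loss-valence stimuli
  th2 <- th
  th2[["pi_av"]] <- -2
  st$V[4] <- 0.5
  expect_equal(action_values(st, "nogo_avoid", th2, sp)[["go"]],
               0.1 - 2 * 0.5)
})

test_that("choice probabilities are a lapse-mixed softmax with hard bounds", {
  expect_equal(action_probabilities(c(0, 0), 0), c(go = 0.5, nogo = 0.5))
  expect_equal(action_probabilities(c(50, -50), 1), c(go = 0.5, nogo = 0.5))
  expect_equal(action_probabilities(c(1, 0), 0)[["go"]],
               1 / (1 + exp(-1)), tolerance = 1e-12)
  set.seed(21)
  for (k in 1:50) {
    v <- rnorm(2, 0, 200)
    xi <- runif(1)
    p <- action_probabilities(v, xi)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p >= xi / 2 - 1e-12 & p <= 1 - xi / 2 + 1e-12))
    expect_false(anyNA(p))
  }
})

test_that("Rescorla-Wagner updates move Q and V toward beta * outcome", {
  sp <- model_spec("dual")
  th <- c(alpha = 0.5, beta = 2, b = 0, xi = 0, pi_app = 0, pi_av = 0)
  st <- update_state(learner_state(), "go_win", "go", 1L, th, sp)
  expect_equal(st$Q["go", 1], 1.0) # 0 + 0.5 * (2 - 0)
  expect_equal(st$V[[1]], 1.0)
  expect_equal(st$Q["nogo", 1], 0) # only the taken action moves
  expect_equal(sum(abs(st$Q[, 2:4])), 0)
  th2 <- c(alpha = 0.1, beta = 1, b = 0, xi = 0, pi_app = 0, pi_av = 0)
  st2 <- update_state(learner_state(), "go_avoid", "nogo", -1L, th2, sp)
  expect_equal(st2$V[[3]], -0.1)
  # missed responses update nothing
  st3 <- update_state(learner_state(), "go_win", "missed", 1L, th, sp)
  expect_equal(sum(abs(st3$Q)) + sum(abs(st3$V)), 0)
})

test_that("a 60-trial state trajectory matches an independent iterative oracle", {
  set.seed(31)
  sp <- model_spec("dual")
  th <- c(alpha = 0.3, beta = 2.5, b = 0.2, xi = 0.1, pi_app = 0.8,
          pi_av = 0.4)
  cond_idx <- sample(1:4, 60, replace = TRUE)
  acts <- sample(0:1, 60, replace = TRUE)
  outs <- sample(c(-1, 0, 1), 60, replace = TRUE)
  # package path
  st <- learner_state()
  lv <- c("go_win", "nogo_win", "go_avoid", "nogo_avoid")
  for (i in 1:60) {
    st <- update_state(st, lv[cond_idx[i]], if (acts[i]) "go" else "nogo",
                       outs[i], th, sp)
  }
  # independent oracle
  Q <- matrix(0, 2, 4)
  V <- rep(0, 4)
  for (i in 1:60) {
    s <- cond_idx[i]
    a <- if (acts[i]) 1 else 2
    Q[a, s] <- Q[a, s] + 0.3 * (2.5 * outs[i] - Q[a, s])
    V[s] <- V[s] + 0.3 * (2.5 * outs[i] - V[s])
  }
  expect_equal(unname(st$Q["go", ]), Q[1, ], tolerance = 1e-12)
  expect_equal(unname(st$Q["nogo", ]), Q[2, ], tolerance = 1e-12)
  expect_equal(unname(st$V), V, tolerance = 1e-12)
})

test_that("likelihood equals log 2 per maximally uncertain first trial", {
  sp <- model_spec("dual")
  th <- c(alpha = 0.2, beta = 3, b = 0, xi = 0, pi_app = 1, pi_av = 1)
  d <- oracle_trials_tibble(1, 1, 1, 1)
  expect_equal(negative_log_likelihood(d, th, sp), log(2), tolerance = 1e-12)
})

test_that("likelihood matches the brute-force oracle on small datasets", {
  set.seed(41)
  sp <- full_spec()
  # all 1- and 2-trial datasets at administration 1
  opts <- expand.grid(cond = 1:4, act = 0:1, out = c(-1, 0, 1))
  p <- random_full_params()
  th <- as_named_params(p)
  for (i in seq_len(nrow(opts))) {
    d <- oracle_trials_tibble(opts$cond[i], opts$act[i], opts$out[i], 1)
    expect_equal(negative_log_likelihood(d, th, sp),
                 oracle_nll(opts$cond[i], opts$act[i], opts$out[i], 1, p),
                 tolerance = 1e-12)
  }
  idx <- expand.grid(i = seq_len(nrow(opts)), j = seq_len(nrow(opts)))
  for (r in sample(nrow(idx), 300)) {
    i <- idx$i[r]; j <- idx$j[r]
    p <- random_full_params()
    th <- as_named_params(p)
    cond <- c(opts$cond[i], opts$cond[j])
    act <- c(opts$act[i], opts$act[j])
    out <- c(opts$out[i], opts$out[j])
    for (admins in list(c(1, 1), c(1, 3), c(3, 4), c(4, 5))) {
      d <- oracle_trials_tibble(cond, act, out, admins)
      expect_equal(negative_log_likelihood(d, th, sp),
                   oracle_nll(cond, act, out, admins, p), tolerance = 1e-12)
    }
  }
})

test_that("richer models with neutral extras reproduce simpler likelihoods", {
  set.seed(51)
  specs <- model_set()
  for (k in 1:30) {
    n <- sample(5:40, 1)
    cond <- sample(1:4, n, replace = TRUE)
    act <- sample(0:1, n, replace = TRUE)
    out <- sample(c(-1, 0, 1), n, replace = TRUE)
    adm <- sort(sample(1:5, n, replace = TRUE))
    d <- oracle_trials_tibble(cond, act, out, adm)
    alpha <- runif(1, 0.05, 0.6); beta <- runif(1, 0.5, 4)
    nll_rw <- negative_log_likelihood(d, c(alpha = alpha, beta = beta),
                                      specs[["RW"]])
    nll_noise <- negative_log_likelihood(
      d, c(alpha = alpha, beta = beta, xi = 0), specs[["RW+noise"]])
    nll_bias <- negative_log_likelihood(
      d, c(alpha = alpha, beta = beta, b = 0, xi = 0),
      specs[["RW+noise+bias"]])
    nll_pav <- negative_log_likelihood(
      d, c(alpha = alpha, beta = beta, b = 0, xi = 0, pi = 0),
      specs[["RW+noise+bias+Pav"]])
    nll_2pav <- negative_log_likelihood(
      d, c(alpha = alpha, beta = beta, b = 0, xi = 0, pi_app = 0,
           pi_av = 0), specs[["RW+noise+bias+2Pav"]])
    nll_sess <- negative_log_likelihood(
      d, c(alpha = alpha, beta = beta, b = 0, xi = 0, pi_app = 0,
           pi_av = 0, pi_app_post = 0, pi_av_post = 0),
      specs[["RW+noise+bias+2Pav+session"]])
    expect_identical(nll_rw, nll_noise)
    expect_identical(nll_noise, nll_bias)
    expect_identical(nll_bias, nll_pav)
    expect_identical(nll_pav, nll_2pav)
    expect_identical(nll_2pav, nll_sess)
    # single pi equals dual with equal weights
    pi <- rnorm(1)
    expect_identical(
      negative_log_likelihood(d, c(alpha = alpha, beta = beta, b = 0.1,
                                   xi = 0.1, pi = pi),
                              specs[["RW+noise+bias+Pav"]]),
      negative_log_likelihood(d, c(alpha = alpha, beta = beta, b = 0.1,
                                   xi = 0.1, pi_app = pi, pi_av = pi),
                              specs[["RW+noise+bias+2Pav"]]))
  }
})

test_that("session-varying weights equal to the pre values change nothing", {
  set.seed(61)
  sp2 <- model_spec("dual")
  sp3 <- full_spec()
  for (k in 1:10) {
    n <- 50
    d <- oracle_trials_tibble(sample(1:4, n, TRUE), sample(0:1, n, TRUE),
                              sample(c(-1, 0, 1), n, TRUE),
                              sort(sample(1:5, n, TRUE)))
    th2 <- c(alpha = 0.3, beta = 2, b = 0.2, xi = 0.05,
             pi_app = rnorm(1), pi_av = rnorm(1))
    th3 <- c(th2, pi_app_post = th2[["pi_app"]],
             pi_av_post = th2[["pi_av"]])
    expect_identical(negative_log_likelihood(d, th2, sp2),
                     negative_log_likelihood(d, th3, sp3))
  }
})

test_that("unordered or malformed trial data is rejected", {
  sp <- model_spec("dual")
  th <- c(alpha = 0.2, beta = 3, b = 0, xi = 0.1, pi_app = 0, pi_av = 0)
  d <- oracle_trials_tibble(c(1, 2), c(1, 0), c(1, 0), c(3, 1))
  expect_error(negative_log_likelihood(d, th, sp), "ordered")
  d2 <- oracle_trials_tibble(c(1, 2), c(1, 0), c(1, 0), c(1, 1))
  d2$trial_index <- c(2L, 1L)
  expect_error(negative_log_likelihood(d2, th, sp), "strictly increasing")
  d3 <- d2
  d3$trial_index <- 1:2
  d3$action[1] <- "left"
  expect_error(negative_log_likelihood(d3, th, sp), "go")
})

test_that("missed responses count as nogo and can skip learning", {
  sp <- model_spec("dual")
  th <- c(alpha = 0.4, beta = 2, b = 0.3, xi = 0.1, pi_app = 0.5,
          pi_av = 0.5)
  d_missed <- oracle_trials_tibble(c(1, 1, 1), c(0, 0, 1), c(-1, -1, 1),
                                   c(1, 1, 1))
  d_missed$action[1] <- "missed"
  d_nogo <- oracle_trials_tibble(c(1, 1, 1), c(0, 0, 1), c(-1, -1, 1),
                                 c(1, 1, 1))
  expect_equal(negative_log_likelihood(d_missed, th, sp),
               negative_log_likelihood(d_nogo, th, sp))
  # with missed_learning = "none" the missed trial's outcome is ignored
  d_short <- oracle_trials_tibble(c(1, 1), c(0, 1), c(-1, 1), c(1, 1))
  ll_skip <- trial_log_probabilities(d_missed, th, sp,
                                     missed_learning = "none")
  ll_short <- trial_log_probabilities(d_short, th, sp)
  expect_equal(ll_skip[3], ll_short[2], tolerance = 1e-12)
})

test_that("generative agents show the expected limiting behaviour", {
  sp <- model_spec("dual")
  # pure-noise agent responds at chance in every condition
  noisy <- simulate_agent_trials(
    c(alpha = 0.2, beta = 3, b = 0, xi = 0.999, pi_app = 0, pi_av = 0),
    sp, n_administrations = 1, n_per_condition = 250, seed = 5)
  rates <- dplyr::summarise(dplyr::group_by(noisy, condition),
                            r = mean(action == "go"))
  expect_true(all(abs(rates$r - 0.5) < 0.1))
  # no learning: go-rate governed by bias and lapse only, flat over trials
  frozen <- simulate_agent_trials(
    c(alpha = 0, beta = 3, b = 0.7, xi = 0.2, pi_app = 2, pi_av = 2),
    sp, n_administrations = 1, n_per_condition = 500, seed = 6)
  p_expected <- plogis(0.7) * 0.8 + 0.1
  expect_lt(abs(mean(frozen$action == "go") - p_expected), 0.035)
})

test_that("appetitive Pavlovian weight invigorates go on no-go-to-win", {
  rates <- vapply(1:100, function(k) {
    sp <- model_spec("dual")
    pav <- simulate_agent_trials(
      c(alpha = 0.25, beta = 3, b = 0.3, xi = 0.05, pi_app = 2, pi_av = 0),
      sp, 1, 20, outcome_rule(variant = "conventional"), seed = 7000 + k)
    flat <- simulate_agent_trials(
      c(alpha = 0.25, beta = 3, b = 0.3, xi = 0.05, pi_app = 0, pi_av = 0),
      sp, 1, 20, outcome_rule(variant = "conventional"), seed = 8000 + k)
    mean(pav$action[pav$condition == "nogo_win"] == "go") -
      mean(flat$action[flat$condition == "nogo_win"] == "go")
  }, numeric(1))
  expect_gt(mean(rates), 0)
  expect_gt(mean(rates > 0), 0.8)
})

test_that("R-level building blocks agree with the compiled likelihood", {
  set.seed(71)
  sp <- full_spec()
  p <- random_full_params()
  th <- as_named_params(p)
  n <- 40
  cond <- sample(1:4, n, TRUE)
  act <- sample(0:1, n, TRUE)
  out <- sample(c(-1, 0, 1), n, TRUE)
  adm <- sort(sample(c(1, 3, 4), n, TRUE))
  d <- oracle_trials_tibble(cond, act, out, adm)
  lv <- c("go_win", "nogo_win", "go_avoid", "nogo_avoid")
  st <- learner_state()
  cur <- -1L
  nll_r <- 0
  for (i in seq_len(n)) {
    if (adm[i] != cur) {
      cur <- adm[i]
      st <- learner_state()
    }
    v <- action_values(st, lv[cond[i]], th, sp, cur)
    pr <- action_probabilities(v, th[["xi"]])
    nll_r <- nll_r - log(if (act[i]) pr[["go"]] else pr[["nogo"]])
    st <- update_state(st, lv[cond[i]], if (act[i]) "go" else "nogo",
                       out[i], th, sp)
  }
  expect_equal(negative_log_likelihood(d, th, sp), nll_r, tolerance = 1e-10)
})
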