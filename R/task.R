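#' The four orthogonalized Go/No-Go conditions
#'
#' The task crosses required action (go / no-go) with outcome valence
#' (win / loss avoidance) in a balanced 2x2 factorial, giving four trial
#' conditions, each tied to a distinct stimulus. `go_win` and `nogo_avoid`
#' are *congruent* (the Pavlovian tendency — approach for reward cues,
#' inhibition for loss cues — agrees with the instrumental requirement);
#' `nogo_win` and `go_avoid` are *incongruent*.
#'
#' @return A tibble with one row per condition and columns `condition`,
#'   `valence` (`"win"`/`"loss"`), `correct_action` (`"go"`/`"nogo"`) and
#'   `congruent` (logical).
#' @export
#' @examples
#' gng_conditions()
gng_conditions <- function() {
  tibble::tibble(
    condition = c("go_win", "nogo_win", "go_avoid", "nogo_avoid"),
    valence = c("win", "win", "loss", "loss"),
    correct_action = c("go", "nogo", "go", "nogo"),
    congruent = c(TRUE, FALSE, FALSE, TRUE)
  )
}

condition_levels <- function() c("go_win", "nogo_win", "go_avoid", "nogo_avoid")

as_condition_index <- function(condition) {
  idx <- match(condition, condition_levels())
  if (anyNA(idx)) {
    bad <- unique(condition[is.na(idx)])
    stop("unknown condition(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  idx
}

#' Probabilistic outcome rule for the Go/No-Go task
#'
#' Feedback is probabilistic: the correct action for a condition yields the
#' better of its two outcomes with probability `dominant_prob` (80% in the
#' standard task). Two variants of the full outcome table are provided.
#' Under `"paper_text"`, the wrong action in a win condition yields a *loss*
#' with probability `dominant_prob` and a reward otherwise; under
#' `"conventional"`, win conditions only ever deliver reward or nothing
#' (and loss conditions loss or nothing), with the wrong action simply
#' reversing the probabilities. Loss-avoidance conditions are identical in
#' the two variants.
#'
#' @param dominant_prob Probability that the correct action yields the
#'   better outcome. Default 0.8.
#' @param variant `"paper_text"` (default) or `"conventional"`.
#' @return A tibble with columns `condition`, `action`, `outcome`
#'   (-1, 0, +1) and `prob`, class `"gng_outcome_rule"`. Probabilities sum
#'   to 1 within each condition x action cell.
#' @export
#' @examples
#' outcome_rule(0.8, "conventional")
outcome_rule <- function(dominant_prob = 0.8,
                         variant = c("paper_text", "conventional")) {
  variant <- match.arg(variant)
  if (!is.numeric(dominant_prob) || length(dominant_prob) != 1L ||
      dominant_prob < 0 || dominant_prob > 1) {
    stop("`dominant_prob` must be a probability", call. = FALSE)
  }
  d <- dominant_prob
  cells <- function(condition, action, outcomes, probs) {
    tibble::tibble(condition = condition, action = action,
                   outcome = outcomes, prob = probs)
  }
  win_wrong <- if (variant == "paper_text") {
    list(outcomes = c(-1L, 1L), probs = c(d, 1 - d))
  } else {
    list(outcomes = c(0L, 1L), probs = c(d, 1 - d))
  }
  rule <- dplyr::bind_rows(
    # win conditions: correct action
    cells("go_win", "go", c(1L, 0L), c(d, 1 - d)),
    cells("nogo_win", "nogo", c(1L, 0L), c(d, 1 - d)),
    # win conditions: wrong action
    cells("go_win", "nogo", win_wrong$outcomes, win_wrong$probs),
    cells("nogo_win", "go", win_wrong$outcomes, win_wrong$probs),
    # loss-avoidance conditions
    cells("go_avoid", "go", c(0L, -1L), c(d, 1 - d)),
    cells("nogo_avoid", "nogo", c(0L, -1L), c(d, 1 - d)),
    cells("go_avoid", "nogo", c(-1L, 0L), c(d, 1 - d)),
    cells("nogo_avoid", "go", c(-1L, 0L), c(d, 1 - d))
  )
  rule <- dplyr::arrange(rule, as_condition_index(.data$condition),
                         .data$action, .data$outcome)
  attr(rule, "dominant_prob") <- d
  attr(rule, "variant") <- variant
  class(rule) <- c("gng_outcome_rule", class(rule))
  rule
}

# 4 x 3 outcome-probability matrices (conditions x outcomes -1/0/+1),
# one per action, for the C++ simulation path.
rule_matrices <- function(rule) {
  out <- list()
  for (a in c("go", "nogo")) {
    m <- matrix(0, nrow = 4, ncol = 3,
                dimnames = list(condition_levels(), c("-1", "0", "1")))
    sub <- rule[rule$action == a, ]
    m[cbind(as_condition_index(sub$condition), sub$outcome + 2L)] <- sub$prob
    out[[a]] <- m
  }
  out
}

#' Sample outcomes from an outcome rule
#'
#' @param condition Character vector of condition labels.
#' @param action Character vector (`"go"`/`"nogo"`), recycled against
#'   `condition`.
#' @param rule An [outcome_rule()].
#' @param n Number of draws when `condition` has length one.
#' @return Integer vector of outcomes in {-1, 0, +1}.
#' @export
#' @examples
#' set.seed(1)
#' table(sample_outcome("nogo_avoid", "nogo", outcome_rule(), n = 1000))
sample_outcome <- function(condition, action, rule = outcome_rule(), n = NULL) {
  if (!is.null(n)) {
    if (length(condition) != 1L || length(action) != 1L) {
      stop("`n` may only be used with scalar `condition`/`action`",
           call. = FALSE)
    }
    condition <- rep(condition, n)
    action <- rep(action, n)
  }
  if (length(action) == 1L) action <- rep(action, length(condition))
  if (!all(action %in% c("go", "nogo"))) {
    stop("`action` must be 'go' or 'nogo'", call. = FALSE)
  }
  mats <- rule_matrices(rule)
  idx <- as_condition_index(condition)
  bad <- vapply(seq_along(idx), function(i) {
    sum(mats[[action[i]]][idx[i], ]) < 1 - 1e-9
  }, logical(1))
  if (any(bad)) {
    stop("outcome rule has no entry for ",
         paste(unique(paste(condition[bad], action[bad])), collapse = ", "),
         call. = FALSE)
  }
  u <- runif(length(idx))
  out <- integer(length(idx))
  for (i in seq_along(idx)) {
    p <- mats[[action[i]]][idx[i], ]
    out[i] <- c(-1L, 0L, 1L)[findInterval(u[i], cumsum(p),
                                          left.open = TRUE) + 1L]
  }
  out
}

#' Generate a trial schedule for one task administration
#'
#' Conditions are interleaved pseudo-randomly by uniformly permuting blocks
#' of four (one trial of each condition per block), which keeps local
#' condition frequencies balanced across the session. The standard session
#' has 60 trials per condition (240 trials).
#'
#' @param n_per_condition Trials per condition (default 60).
#' @param seed Optional integer seed; identical seeds give identical
#'   schedules. The caller's RNG state is restored.
#' @return A tibble with columns `trial_index` and `condition`.
#' @export
#' @examples
#' generate_schedule(2, seed = 1)
generate_schedule <- function(n_per_condition = 60, seed = NULL) {
  if (!is.numeric(n_per_condition) || length(n_per_condition) != 1L ||
      n_per_condition < 1 || n_per_condition != round(n_per_condition)) {
    stop("`n_per_condition` must be a positive integer", call. = FALSE)
  }
  with_seed(seed, {
    blocks <- replicate(n_per_condition, sample.int(4L), simplify = FALSE)
    idx <- unlist(blocks)
    tibble::tibble(
      trial_index = seq_along(idx),
      condition = condition_levels()[idx]
    )
  })
}

validate_policy_probs <- function(p, trial) {
  if (!is.numeric(p) || length(p) != 2L || anyNA(p) || any(!is.finite(p)) ||
      any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    stop("policy returned invalid action probabilities at trial ", trial,
         ": [", paste(signif(p, 4), collapse = ", "), "]", call. = FALSE)
  }
}

#' Simulate one task session under an arbitrary policy
#'
#' The policy owns its learning state: it is either a function
#' `function(condition)` returning `c(go = p, nogo = p)` or an agent list
#' with elements `act(condition)`, and optionally `update(condition,
#' action, outcome)` and `reset(administration)` (see [make_agent()]).
#'
#' @param policy Policy function or agent list.
#' @param schedule A [generate_schedule()] tibble.
#' @param rule An [outcome_rule()].
#' @param seed Optional seed (caller's RNG state restored).
#' @param administration Administration number passed to `policy$reset()`.
#' @return A tibble of trial records: `trial_index`, `condition`, `action`,
#'   `outcome`, `rt` (always `NA`; this simulator does not model response
#'   times).
#' @export
#' @examples
#' always_go <- function(condition) c(go = 1, nogo = 0)
#' simulate_session(always_go, generate_schedule(2, seed = 1), seed = 2)
simulate_session <- function(policy, schedule, rule = outcome_rule(),
                             seed = NULL, administration = 1L) {
  act <- if (is.function(policy)) policy else policy$act
  update <- if (is.list(policy)) policy$update else NULL
  if (is.list(policy) && !is.null(policy$reset)) policy$reset(administration)
  mats <- rule_matrices(rule)
  with_seed(seed, {
    n <- nrow(schedule)
    actions <- character(n)
    outcomes <- integer(n)
    for (i in seq_len(n)) {
      cond <- schedule$condition[i]
      p <- act(cond)
      validate_policy_probs(p, schedule$trial_index[i])
      a <- if (runif(1) < p[[1]]) "go" else "nogo"
      probs <- mats[[a]][as_condition_index(cond), ]
      r <- c(-1L, 0L, 1L)[findInterval(runif(1), cumsum(probs),
                                       left.open = TRUE) + 1L]
      actions[i] <- a
      outcomes[i] <- r
      if (!is.null(update)) update(cond, a, r)
    }
    tibble::tibble(
      trial_index = schedule$trial_index,
      condition = schedule$condition,
      action = actions,
      outcome = outcomes,
      rt = NA_real_
    )
  })
}
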