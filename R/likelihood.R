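#' Create an empty learner state
#'
#' Action values `Q` (2 actions x 4 stimuli) and Pavlovian stimulus values
#' `V` (4 stimuli) all start at zero at the beginning of each task
#' administration.
#'
#' @return A list with matrix `Q` (rows `go`/`nogo`) and vector `V`.
#' @export
learner_state <- function() {
  list(
    Q = matrix(0, nrow = 2, ncol = 4,
               dimnames = list(c("nogo", "go"), condition_levels())),
    V = setNames(numeric(4), condition_levels())
  )
}

#' Action values for one stimulus
#'
#' The go action's value is `Q(go, s) + b + pi_eff * V(s)`: the go bias and
#' the Pavlovian stimulus value (weighted by the administration-specific
#' effective Pavlovian parameter for the stimulus's valence) attach to the
#' go action only. The nogo value is the bare instrumental `Q(nogo, s)`.
#'
#' @param state A [learner_state()].
#' @param condition Condition label.
#' @param params Named natural-scale parameter vector.
#' @param spec A [model_spec()].
#' @param administration Integer in 1..5.
#' @return Named numeric vector `c(go = , nogo = )`.
#' @export
action_values <- function(state, condition, params, spec, administration = 1) {
  idx <- as_condition_index(condition)
  stopifnot(length(idx) == 1L)
  slots <- par_slots(params, spec)
  pis <- effective_pavlovian(params, spec, administration)
  win <- gng_conditions()$valence[idx] == "win"
  pi_eff <- if (win) pis[["pi_app"]] else pis[["pi_av"]]
  c(go = unname(state$Q["go", idx] + slots[3] + pi_eff * state$V[idx]),
    nogo = unname(state$Q["nogo", idx]))
}

#' Choice probabilities from a pair of action values
#'
#' A softmax over the two values mixed with a uniform lapse:
#' `p <- softmax(values) * (1 - xi) + xi / 2`. Each probability is
#' guaranteed to lie in `[xi/2, 1 - xi/2]` and the pair sums to one.
#'
#' @param values Numeric pair `(go, nogo)`.
#' @param xi Lapse probability in `[0, 1]`.
#' @return Named probability pair `c(go = , nogo = )`.
#' @export
#' @examples
#' action_probabilities(c(1, 0), xi = 0.1)
action_probabilities <- function(values, xi = 0) {
  if (any(!is.finite(values)) || length(values) != 2L) {
    stop("`values` must be two finite numbers", call. = FALSE)
  }
  if (xi < 0 || xi > 1) stop("`xi` must be in [0, 1]", call. = FALSE)
  m <- max(values)
  e <- exp(values - m)
  p <- e / sum(e)
  p <- p * (1 - xi) + xi / 2
  c(go = p[[1]], nogo = p[[2]])
}

#' Rescorla-Wagner update of the learner state
#'
#' Both the instrumental value of the taken action and the Pavlovian value
#' of the stimulus move toward `beta * outcome` by a fraction `alpha`
#' (the loss-valence learning rate if the spec splits them):
#' `Q(a, s) <- Q(a, s) + alpha * (beta * r - Q(a, s))` and likewise for
#' `V(s)`. A missed response updates nothing.
#'
#' @inheritParams action_values
#' @param action `"go"`, `"nogo"` or `"missed"`.
#' @param outcome Outcome in -1, 0, +1.
#' @return The updated state.
#' @export
update_state <- function(state, condition, action, outcome, params, spec) {
  if (action == "missed") return(state)
  if (!action %in% c("go", "nogo")) {
    stop("`action` must be 'go', 'nogo' or 'missed'", call. = FALSE)
  }
  idx <- as_condition_index(condition)
  slots <- par_slots(params, spec)
  win <- gng_conditions()$valence[idx] == "win"
  alpha <- if (win) slots[1] else slots[9]
  target <- slots[2] * outcome
  state$Q[action, idx] <- state$Q[action, idx] +
    alpha * (target - state$Q[action, idx])
  state$V[idx] <- state$V[idx] + alpha * (target - state$V[idx])
  state
}

# Validate and marshal a subject's trial tibble for the C++ kernel.
# Requires columns condition, action, outcome, administration (trial_index
# used for ordering checks when present). Returns integer/double vectors.
marshal_trials <- function(data, missed_learning = c("nogo", "none")) {
  missed_learning <- match.arg(missed_learning)
  req <- c("condition", "action", "outcome", "administration")
  missing <- setdiff(req, names(data))
  if (length(missing)) {
    stop("trial data lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  adm <- data$administration
  if (is.unsorted(adm)) {
    stop("trial data must be ordered by administration then trial_index",
         call. = FALSE)
  }
  if ("trial_index" %in% names(data)) {
    ok <- unlist(tapply(data$trial_index, adm,
                        function(x) !is.unsorted(x, strictly = TRUE)),
                 use.names = FALSE)
    if (!all(ok)) {
      stop("trial_index must be strictly increasing within administration",
           call. = FALSE)
    }
  }
  if (!all(data$action %in% c("go", "nogo", "missed"))) {
    stop("`action` must be 'go', 'nogo' or 'missed'", call. = FALSE)
  }
  idx <- as_condition_index(data$condition)
  list(
    condition = as.integer(idx),
    valence_win = as.integer(gng_conditions()$valence[idx] == "win"),
    action_go = as.integer(data$action == "go"),
    outcome = as.double(data$outcome),
    administration = as.integer(adm),
    learn = if (missed_learning == "nogo") {
      rep(1L, nrow(data))
    } else {
      as.integer(data$action != "missed")
    }
  )
}

#' Negative log-likelihood of one subject's choices
#'
#' Accumulates `-log p(observed action)` trial by trial under the model
#' defined by `spec` and `params`, resetting the learner state at the start
#' of each administration and applying the administration-specific
#' effective Pavlovian weights. Missed responses are treated as nogo
#' choices; by default they also drive learning (set
#' `missed_learning = "none"` to skip their value updates).
#'
#' @param data Trial tibble for one subject with columns `condition`,
#'   `action`, `outcome`, `administration` (and optionally `trial_index`),
#'   ordered by administration then trial index.
#' @param params Named natural-scale parameter vector.
#' @param spec A [model_spec()].
#' @param missed_learning `"nogo"` (default) or `"none"`.
#' @return Scalar negative log-likelihood; `Inf` (with a warning) if an
#'   observed action has probability zero, which can only happen at
#'   `xi = 0`.
#' @export
negative_log_likelihood <- function(data, params, spec,
                                    missed_learning = "nogo") {
  ll <- trial_log_probabilities(data, params, spec, missed_learning)
  nll <- -sum(ll)
  if (!is.finite(nll)) {
    warning("likelihood underflow: an observed action had probability 0 ",
            "(xi = 0 with a saturated softmax)", call. = FALSE)
  }
  nll
}

#' Per-trial log-probabilities of the observed choices
#'
#' @inheritParams negative_log_likelihood
#' @return Numeric vector, one log-probability per trial.
#' @export
trial_log_probabilities <- function(data, params, spec,
                                    missed_learning = "nogo") {
  m <- marshal_trials(data, missed_learning)
  slots <- par_slots(params, spec)
  cpp_trial_loglik(m$condition, m$valence_win, m$action_go, m$outcome,
                   m$administration, m$learn, slots)
}
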