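#' Specify a member of the nested Go/No-Go learning-model family
#'
#' The family starts from plain Rescorla-Wagner instrumental learning
#' (learning rate `alpha`, reward sensitivity `beta`, with `beta * r`
#' entering the update) and adds, in order: an irreducible noise (lapse)
#' parameter `xi`, a fixed go bias `b`, a Pavlovian influence of the
#' stimulus value on the go action — either one weight `pi` for all
#' stimuli or separate appetitive (`pi_app`, win stimuli) and aversive
#' (`pi_av`, loss stimuli) weights — and finally session variation, where
#' `pi_app` may take a new value (`pi_app_post`) from task administration 3
#' onward and `pi_av` a new value (`pi_av_post`) from administration 4
#' onward. All other parameters are shared across administrations.
#'
#' Exploratory variants with a separate learning rate or lapse for
#' loss-valence stimuli can be switched on via `split_alpha` / `split_xi`;
#' both are off by default.
#'
#' @param pavlovian `"none"`, `"single"` or `"dual"`.
#' @param has_noise Include the lapse parameter `xi`?
#' @param has_bias Include the go bias `b`?
#' @param session_varying Allow the Pavlovian weights to change across
#'   administrations (requires `pavlovian = "dual"`)?
#' @param split_alpha,split_xi Separate `alpha_loss` / `xi_loss` for
#'   loss-valence stimuli (exploratory; default off).
#' @return An object of class `"gng_model_spec"`.
#' @seealso [model_set()], [parameter_names()]
#' @export
#' @examples
#' model_spec("dual", session_varying = TRUE)
model_spec <- function(pavlovian = c("none", "single", "dual"),
                       has_noise = TRUE, has_bias = TRUE,
                       session_varying = FALSE,
                       split_alpha = FALSE, split_xi = FALSE) {
  pavlovian <- match.arg(pavlovian)
  if (session_varying && pavlovian != "dual") {
    stop("session-varying Pavlovian weights require `pavlovian = \"dual\"`",
         call. = FALSE)
  }
  structure(
    list(pavlovian = pavlovian, has_noise = has_noise, has_bias = has_bias,
         session_varying = session_varying, split_alpha = split_alpha,
         split_xi = split_xi),
    class = "gng_model_spec"
  )
}

#' @export
print.gng_model_spec <- function(x, ...) {
  cat("<gng_model_spec>", model_name(x), "\n")
  cat("  parameters:", paste(parameter_names(x), collapse = ", "), "\n")
  invisible(x)
}

#' Parameter names implied by a model specification
#'
#' @param spec A [model_spec()].
#' @return Character vector of parameter names, in canonical order.
#' @export
parameter_names <- function(spec) {
  stopifnot(inherits(spec, "gng_model_spec"))
  nm <- c("alpha", "beta")
  if (spec$has_bias) nm <- c(nm, "b")
  if (spec$has_noise) nm <- c(nm, "xi")
  nm <- switch(spec$pavlovian,
    none = nm,
    single = c(nm, "pi"),
    dual = c(nm, "pi_app", "pi_av")
  )
  if (spec$session_varying) nm <- c(nm, "pi_app_post", "pi_av_post")
  if (spec$split_alpha) nm <- c(nm, "alpha_loss")
  if (spec$split_xi) nm <- c(nm, "xi_loss")
  nm
}

#' Canonical name of a model specification
#'
#' @param spec A [model_spec()].
#' @return A string such as `"RW+noise+bias+2Pav+session"`.
#' @export
model_name <- function(spec) {
  stopifnot(inherits(spec, "gng_model_spec"))
  nm <- "RW"
  if (spec$has_noise) nm <- paste0(nm, "+noise")
  if (spec$has_bias) nm <- paste0(nm, "+bias")
  nm <- switch(spec$pavlovian, none = nm, single = paste0(nm, "+Pav"),
               dual = paste0(nm, "+2Pav"))
  if (spec$session_varying) nm <- paste0(nm, "+session")
  if (spec$split_alpha) nm <- paste0(nm, "+splitAlpha")
  if (spec$split_xi) nm <- paste0(nm, "+splitXi")
  nm
}

#' Build the standard ladder of nested models
#'
#' @param names Canonical model names; defaults to the full six-model
#'   ladder from plain Rescorla-Wagner to the session-varying
#'   dual-Pavlovian model.
#' @return Named list of [model_spec()] objects.
#' @export
#' @examples
#' names(model_set())
model_set <- function(names = c("RW", "RW+noise", "RW+noise+bias",
                                "RW+noise+bias+Pav", "RW+noise+bias+2Pav",
                                "RW+noise+bias+2Pav+session")) {
  build <- function(nm) {
    switch(nm,
      "RW" = model_spec("none", has_noise = FALSE, has_bias = FALSE),
      "RW+noise" = model_spec("none", has_noise = TRUE, has_bias = FALSE),
      "RW+noise+bias" = model_spec("none"),
      "RW+noise+bias+Pav" = model_spec("single"),
      "RW+noise+bias+2Pav" = model_spec("dual"),
      "RW+noise+bias+2Pav+session" = model_spec("dual", session_varying = TRUE),
      stop("unknown model name: ", nm, call. = FALSE)
    )
  }
  setNames(lapply(names, build), names)
}

# Which parameters live on a bounded scale.
unit_params <- function() c("alpha", "xi", "alpha_loss", "xi_loss")
positive_params <- function() "beta"

#' Map parameters between natural and unconstrained scales
#'
#' The hierarchical prior is Gaussian on an unconstrained scale: learning
#' rates and the lapse (`alpha`, `xi`) are logit-transformed, the reward
#' sensitivity `beta` is log-transformed, and the go bias and Pavlovian
#' weights are left untouched. The two maps are exact inverses.
#'
#' @param params Named numeric vector on the natural scale
#'   (`transform_params`) or unconstrained scale (`untransform_params`).
#' @param spec A [model_spec()]; names must match [parameter_names()].
#' @return Named numeric vector on the other scale.
#' @export
#' @examples
#' sp <- model_spec("dual")
#' th <- c(alpha = 0.2, beta = 3, b = 0.3, xi = 0.05, pi_app = 0.5, pi_av = 0.5)
#' untransform_params(transform_params(th, sp), sp)
transform_params <- function(params, spec) {
  nm <- parameter_names(spec)
  params <- check_param_vector(params, nm)
  out <- params
  u <- intersect(nm, unit_params())
  out[u] <- qlogis(params[u])
  p <- intersect(nm, positive_params())
  out[p] <- log(params[p])
  out
}

#' @rdname transform_params
#' @export
untransform_params <- function(params, spec) {
  nm <- parameter_names(spec)
  params <- check_param_vector(params, nm)
  out <- params
  u <- intersect(nm, unit_params())
  out[u] <- plogis(params[u])
  p <- intersect(nm, positive_params())
  out[p] <- exp(params[p])
  out
}

check_param_vector <- function(params, nm) {
  params <- unlist(params)
  if (is.null(names(params))) {
    if (length(params) != length(nm)) {
      stop("expected ", length(nm), " parameters (", paste(nm, collapse = ", "),
           ")", call. = FALSE)
    }
    names(params) <- nm
  }
  missing <- setdiff(nm, names(params))
  if (length(missing)) {
    stop("missing parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(params[nm]))) {
    stop("parameters must be finite", call. = FALSE)
  }
  params[nm]
}

# Expand a named natural-scale parameter vector into the fixed 10-slot
# layout used by the C++ kernels, filling neutral values for inactive
# components (b = 0, xi = 0, pi = 0, post = pre, split = shared).
par_slots <- function(params, spec) {
  params <- check_param_vector(params, parameter_names(spec))
  slots <- numeric(10)
  slots[1] <- params[["alpha"]]
  slots[2] <- params[["beta"]]
  slots[3] <- if (spec$has_bias) params[["b"]] else 0
  slots[4] <- if (spec$has_noise) params[["xi"]] else 0
  if (spec$pavlovian == "single") {
    slots[5] <- slots[6] <- params[["pi"]]
  } else if (spec$pavlovian == "dual") {
    slots[5] <- params[["pi_app"]]
    slots[6] <- params[["pi_av"]]
  }
  if (spec$session_varying) {
    slots[7] <- params[["pi_app_post"]]
    slots[8] <- params[["pi_av_post"]]
  } else {
    slots[7] <- slots[5]
    slots[8] <- slots[6]
  }
  slots[9] <- if (spec$split_alpha) params[["alpha_loss"]] else slots[1]
  slots[10] <- if (spec$split_xi) params[["xi_loss"]] else slots[4]
  slots
}

#' Effective Pavlovian weights at a given administration
#'
#' In the session-varying model the appetitive weight switches from
#' `pi_app` to `pi_app_post` at administration 3 (when the reward-focused
#' phase of therapy has begun) and the aversive weight from `pi_av` to
#' `pi_av_post` at administration 4 (the avoidance-focused phase). Without
#' session variation the weights pass through unchanged.
#'
#' @param params Named natural-scale parameter vector.
#' @param spec A [model_spec()].
#' @param administration Integer in 1..5.
#' @return Named numeric vector `c(pi_app, pi_av)` in effect for that
#'   administration (a single-`pi` model returns its `pi` in both slots;
#'   a model with no Pavlovian component returns zeros).
#' @export
#' @examples
#' sp <- model_spec("dual", session_varying = TRUE)
#' th <- c(alpha = .2, beta = 3, b = .3, xi = .05,
#'         pi_app = 0.5, pi_av = 0.5, pi_app_post = 1, pi_av_post = 1)
#' effective_pavlovian(th, sp, administration = 3)
effective_pavlovian <- function(params, spec, administration) {
  if (!is.numeric(administration) || length(administration) != 1L ||
      !administration %in% 1:5) {
    stop("`administration` must be an integer in 1..5", call. = FALSE)
  }
  slots <- par_slots(params, spec)
  app <- if (spec$session_varying && administration >= 3) slots[7] else slots[5]
  av <- if (spec$session_varying && administration >= 4) slots[8] else slots[6]
  if (spec$pavlovian == "none") c(pi_app = 0, pi_av = 0)
  else c(pi_app = app, pi_av = av)
}
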